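# Flatten a list of maps/matrices into an n_subjects x n_pixels matrix of
# in-mask values (pixel order = which(mask), column-major).
.stack_matrix <- function(stack, template) {
  idx <- which(template$mask)
  rows <- lapply(stack, function(m) {
    v <- if (is.matrix(m)) m else m$values
    if (!identical(dim(v), dim(template$mask))) stop("shape mismatch in stack")
    v[idx]
  })
  do.call(rbind, rows)
}

# Core one-sample t computation on an n x p matrix (null mean 0).
# Zero-variance pixels are invalid: t/p/z are placeholders there.
.tmap_core <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  ctr <- sweep(X, 2, m)
  v <- colSums(ctr^2) / (n - 1)
  valid <- v > 0
  t <- ifelse(valid, m / sqrt(v / n), 0)
  list(t = t, valid = valid, n = n)
}

.full_matrix <- function(vals, template, fill = 0) {
  out <- matrix(fill, template$height, template$width)
  out[template$mask] <- vals
  out
}

#' Pixel-wise one-sample t-map within the body mask
#'
#' Random-effects group statistic: at every in-mask pixel, the subject
#' values are tested against a null mean of zero with a one-sample t-test
#' (`df = n - 1`). Pixels where all subjects agree exactly (typically:
#' nobody marked anything) have zero variance and are flagged invalid
#' rather than forced to t = 0; they are excluded from thresholding.
#' Two-sided p-values and the matching Z-scores (see [t_to_z()]) are
#' filled in.
#'
#' @param stack list of per-subject matrices, [sensation_map()]s, or
#'   baseline differences (`bsm_diff`); at least 3 subjects.
#' @param template a [body_template()].
#' @param kind statistic label, `"one-sample"` or `"paired"`.
#' @return object of class `bsm_stat` with matrix layers `t`, `p`, `z`,
#'   `valid` and scalars `df`, `n`, `kind`.
#' @export
one_sample_tmap <- function(stack, template, kind = "one-sample") {
  if (length(stack) < 3) stop("at least 3 subjects are required")
  X <- .stack_matrix(stack, template)
  core <- .tmap_core(X)
  df <- core$n - 1L
  p <- ifelse(core$valid, 2 * pt(abs(core$t), df, lower.tail = FALSE), 1)
  z <- ifelse(core$valid, t_to_z(core$t, df), 0)
  structure(list(t = .full_matrix(core$t, template),
                 p = .full_matrix(p, template, fill = 1),
                 z = .full_matrix(z, template),
                 valid = .full_matrix(core$valid, template) > 0,
                 df = df, n = core$n, kind = kind,
                 template = template),
            class = "bsm_stat")
}

#' Pixel-wise paired t-map
#'
#' Paired comparison of two session stacks (same subjects, same order),
#' e.g. stimulation sessions against the baseline session. Identical to
#' [one_sample_tmap()] applied to the per-subject differences A - B.
#'
#' @param stack_a,stack_b lists of per-subject matrices or maps, aligned
#'   by subject.
#' @inheritParams one_sample_tmap
#' @return a `bsm_stat` with `kind = "paired"`.
#' @export
paired_tmap <- function(stack_a, stack_b, template) {
  if (length(stack_a) != length(stack_b))
    stop("paired stacks must have the same number of subjects")
  ids_a <- vapply(stack_a, function(m) if (is.matrix(m)) NA_character_ else m$subject_id, character(1))
  ids_b <- vapply(stack_b, function(m) if (is.matrix(m)) NA_character_ else m$subject_id, character(1))
  if (!anyNA(ids_a) && !anyNA(ids_b) && !identical(ids_a, ids_b))
    stop("paired stacks must list the same subjects in the same order")
  diffs <- Map(function(a, b) {
    va <- if (is.matrix(a)) a else a$values
    vb <- if (is.matrix(b)) b else b$values
    va - vb
  }, stack_a, stack_b)
  one_sample_tmap(diffs, template, kind = "paired")
}

#' Transform t-statistics to Z-scores
#'
#' Maps each t-value to the standard-normal deviate carrying the same
#' two-sided tail probability: `z = sign(t) * qnorm(1 - p_two/2)`. The
#' transformation is monotone in t, symmetric (`t = 0` maps to `z = 0`),
#' and satisfies `|z| <= |t|` for `df >= 2` since the t distribution has
#' heavier tails. Computed on the log scale so large |t| does not
#' saturate.
#'
#' @param t numeric vector/matrix of t-statistics, or a `bsm_stat` whose
#'   `z` layer should be (re)computed.
#' @param df degrees of freedom (ignored when `t` is a `bsm_stat`).
#' @return Z-scores matching `t`, or the updated `bsm_stat`.
#' @export
t_to_z <- function(t, df = NULL) {
  if (inherits(t, "bsm_stat")) {
    stat <- t
    z <- t_to_z(stat$t, stat$df)
    z[!stat$valid] <- 0
    stat$z <- z
    return(stat)
  }
  if (is.null(df) || df < 1) stop("df must be >= 1")
  lt <- pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  sign(t) * qnorm(lt, lower.tail = FALSE, log.p = TRUE)
}

#' @export
print.bsm_stat <- function(x, ...) {
  cat(sprintf("<bsm_stat> %s t-map, n = %d, df = %d, %d valid pixels, max |z| = %.3f\n",
              x$kind, x$n, x$df, sum(x$valid), max(abs(x$z))))
  invisible(x)
}

#' Export the layers of a statistic map
#'
#' Writes per-layer CSV matrices (`t`, `p`, `z`, `valid`) plus a JSON
#' metadata file (`kind`, `df`, `n`), or a single RDS container.
#'
#' @param stat a `bsm_stat`.
#' @param path output directory (CSV layers) or `.rds` file path.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(stat, path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(stat, path)
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (layer in c("t", "p", "z", "valid")) {
    m <- stat[[layer]] + 0       # t and z are signed; valid coerced to 0/1
    txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    write.table(txt, file.path(path, paste0(layer, ".csv")), sep = ",",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(list(kind = stat$kind, df = stat$df, n = stat$n),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}
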