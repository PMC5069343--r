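#' Rendering options for Z-maps
#'
#' @param zlim symmetric display range for Z; `NULL` = +/- max |z| of the
#'   colored pixels (diverging palette centered at z = 0).
#' @param show_surviving_only when clusters are supplied, color only
#'   pixels in surviving clusters.
#' @param outline draw the body outline (mask boundary) in black.
#' @param marker optional `(row, col)` of the stimulus site to mark.
#' @return list of class `bsm_render_spec`.
#' @export
render_spec <- function(zlim = NULL, show_surviving_only = TRUE,
                        outline = TRUE, marker = NULL) {
  if (!is.null(zlim) && zlim[1] >= zlim[2]) stop("zlim must satisfy min < max")
  structure(list(zlim = zlim, show_surviving_only = show_surviving_only,
                 outline = outline, marker = marker),
            class = "bsm_render_spec")
}

.mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  interior <- pad[2:(h + 1), 2:(w + 1)] & pad[1:h, 2:(w + 1)] &
    pad[3:(h + 2), 2:(w + 1)] & pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  mask & !interior
}

.diverging_palette <- function(n = 255L) {
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  ramp(seq(0, 1, length.out = n)) / 255
}

#' Render a Z-score topography on the body outline
#'
#' Deterministic raster rendering: gray body silhouette, black outline,
#' and in-mask pixels colored by Z on a diverging palette centered at
#' zero. When a cluster set is supplied with `show_surviving_only`, only
#' pixels inside surviving clusters are colored, reproducing the
#' corrected-map view.
#'
#' @param stat a `bsm_stat` with a `z` layer.
#' @param clusters optional `bsm_cluster_set`.
#' @param template a [body_template()].
#' @param spec a [render_spec()].
#' @param path optional PNG output path.
#' @return h x w x 3 numeric array in \[0, 1\], invisibly.
#' @export
render_zmap <- function(stat, clusters = NULL, template, spec = render_spec(),
                        path = NULL) {
  if (is.null(stat$z)) stop("stat map has no z layer")
  h <- template$height; w <- template$width
  colored <- template$mask & stat$valid & (stat$z != 0)
  if (!is.null(clusters) && spec$show_surviving_only) {
    surv <- matrix(FALSE, h, w)
    for (i in clusters$surviving) surv <- surv | (clusters$labels == i)
    colored <- colored & surv
  }
  img <- array(1, dim = c(h, w, 3))                       # white background
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[template$mask] <- 0.88                          # gray silhouette
    img[, , ch] <- plane
  }
  if (any(colored)) {
    zmax <- if (is.null(spec$zlim)) max(abs(stat$z[colored])) else max(abs(spec$zlim))
    pal <- .diverging_palette()
    zi <- pmax(pmin(stat$z[colored] / zmax, 1), -1)
    ci <- pmin(nrow(pal), pmax(1, round((zi + 1) / 2 * (nrow(pal) - 1)) + 1))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[colored] <- pal[ci, ch]
      img[, , ch] <- plane
    }
  }
  if (spec$outline) {
    bd <- .mask_boundary(template$mask)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[bd] <- 0
      img[, , ch] <- plane
    }
  }
  if (!is.null(spec$marker)) {
    r <- spec$marker[1]; c <- spec$marker[2]
    rows <- max(1, r - 1):min(h, r + 1); cols <- max(1, c - 1):min(w, c + 1)
    img[rows, cols, 1] <- 1; img[rows, cols, 2] <- 0.55; img[rows, cols, 3] <- 0
  }
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}

#' Render the item-by-condition intensity matrix as a heatmap
#'
#' @param means matrix from [intensity_matrix()].
#' @param path optional PNG output path.
#' @param cell pixel size of one matrix cell.
#' @return raster array, invisibly.
#' @export
render_intensity_matrix <- function(means, path = NULL, cell = 16L) {
  pal <- .diverging_palette()
  v <- pmax(pmin(means / 3, 1), 0)                        # scores live in 0..3
  ci <- round(v * (nrow(pal) - 1)) + 1
  img <- array(1, dim = c(nrow(means) * cell, ncol(means) * cell, 3))
  for (i in seq_len(nrow(means))) for (j in seq_len(ncol(means))) {
    rows <- ((i - 1) * cell + 1):(i * cell)
    cols <- ((j - 1) * cell + 1):(j * cell)
    for (ch in 1:3) img[rows, cols, ch] <- pal[ci[i, j], ch]
  }
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}

#' Run the full analysis pipeline from a config
#'
#' Executes preprocess, pixel-wise statistics, Monte-Carlo cluster-extent
#' correction and rendering for every condition, for the contrasts listed
#' in the config (`"vs-zero"`: normalized maps against zero;
#' `"vs-baseline"`: baseline-subtracted differences against zero), and
#' writes all tables, null distributions, images and a reproducibility
#' log under `out_dir`.
#'
#' Config keys (YAML file or list): `template` (builtin name, path, or
#' a synthetic spec `list(width, height, style, n_views)`), one of
#' `manifest` (+ optional `questionnaire`) or `simulate`
#' (`study_design()` arguments plus `seed`), `contrasts`, and `mc`
#' ([mc_config()] arguments; `fwhm_px` defaults to the estimated residual
#' smoothness of the analyzed stack).
#'
#' @param config path to a YAML file or an equivalent named list.
#' @param out_dir output directory.
#' @return invisibly, a list with the per-contrast cluster tables and the
#'   paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  template <- .resolve_template(config$template)
  if (!is.null(config$manifest)) {
    dataset <- load_dataset(config$manifest, template, config$questionnaire)
    truth <- NULL
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    seed <- sim$seed %||% 1L
    sim$seed <- NULL
    design <- do.call(study_design, sim)
    gs <- generate_study(template, design, seed = seed)
    dataset <- gs$dataset
    truth <- gs$truth
  } else stop("config needs either `manifest` or `simulate`")
  contrasts <- config$contrasts %||% c("vs-zero", "vs-baseline")
  mc_args <- config$mc %||% list()
  conds <- unique(do.call(rbind, lapply(dataset$maps, function(m)
    if (m$session_kind == "stimulation")
      data.frame(stimulus_type = m$stimulus_type, location = m$stimulus_location))))
  results <- list()
  log <- list(contrasts = contrasts, conditions = conds, mc = mc_args,
              provenance = dataset$provenance, config = config)
  for (contrast in contrasts) {
    bc <- contrast == "vs-baseline"
    stacks <- lapply(seq_len(nrow(conds)), function(i)
      condition_stack(dataset, conds$stimulus_type[i], conds$location[i],
                      baseline_correct = bc))
    # one null simulation per contrast; smoothness estimated from the
    # pooled residuals of the first condition unless given explicitly
    if (is.null(mc_args$fwhm_px))
      mc_args$fwhm_px <- estimate_fwhm(stacks[[1]], template)
    cfg <- do.call(mc_config, mc_args)
    null <- simulate_null_max_clusters(template, cfg)
    thr <- cluster_threshold(null)
    write_null_distribution(null, file.path(out_dir, paste0("null_", contrast, ".csv")))
    log[[contrast]] <- list(fwhm_px = cfg$fwhm_px,
                            extent_threshold = thr$extent_threshold,
                            achieved = thr$achieved)
    for (i in seq_len(nrow(conds))) {
      tag <- paste(contrast, conds$stimulus_type[i], conds$location[i], sep = "_")
      stat <- one_sample_tmap(stacks[[i]], template)
      cl <- extract_clusters(stat, template, cfg, thr$extent_threshold)
      tab <- cluster_table(cl, template)
      utils::write.csv(tab, file.path(out_dir, paste0("clusters_", tag, ".csv")),
                       row.names = FALSE)
      render_zmap(stat, cl, template, render_spec(),
                  path = file.path(out_dir, paste0("zmap_", tag, ".png")))
      results[[tag]] <- tab
    }
  }
  if (!is.null(dataset$questionnaire)) {
    an <- deqi_anova(dataset$questionnaire)
    utils::write.csv(an, file.path(out_dir, "deqi_anova.csv"), row.names = FALSE)
    im <- intensity_matrix(dataset$questionnaire)
    utils::write.csv(im, file.path(out_dir, "deqi_intensity_matrix.csv"))
    render_intensity_matrix(im, file.path(out_dir, "deqi_intensity_matrix.png"))
    results$deqi_anova <- an
  }
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(results)
}

.resolve_template <- function(x) {
  if (is.null(x)) return(load_template("default-1024"))
  if (inherits(x, "bsm_template")) return(x)
  if (is.list(x)) return(do.call(make_synthetic_template, x))
  load_template(x)
}
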