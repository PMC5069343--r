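#' Configuration for Monte-Carlo cluster-extent correction
#'
#' Bundles the parameters of the cluster-extent multiple-comparison
#' procedure: pixels are thresholded at an uncorrected per-pixel p-value
#' and only connected components larger than an extent cutoff — read off
#' the null distribution of maximum cluster sizes over simulated smooth
#' Gaussian fields — are declared significant, controlling the
#' family-wise error across the whole body map.
#'
#' @param n_iterations number of simulated null fields (default 10000).
#' @param voxel_p uncorrected per-pixel threshold (default 0.05).
#' @param corrected_alpha target family-wise error rate (default 0.05).
#' @param fwhm_px smoothness (FWHM, pixels) of the simulated null fields;
#'   set from [estimate_fwhm()] of the data residuals when known.
#' @param connectivity 4 or 8 (default 8: edge + diagonal adjacency).
#' @param sides `"two"` (threshold two-sided, `|z| > qnorm(1 - p/2)`) or
#'   `"one"` (`z > qnorm(1 - p)`). With `sides = "two"` the simulated
#'   suprathreshold rate equals `voxel_p` across both tails.
#' @param positive_only restrict data cluster extraction to positive-t
#'   clusters ("sensation present"); the null maximum over both tails is
#'   at least the positive-tail maximum, so the extent threshold remains
#'   valid (conservative) for one-signed extraction.
#' @param seed RNG seed for the simulation.
#' @return object of class `bsm_mc_config`.
#' @export
mc_config <- function(n_iterations = 10000L, voxel_p = 0.05,
                      corrected_alpha = 0.05, fwhm_px = 0,
                      connectivity = 8L, sides = c("two", "one"),
                      positive_only = TRUE, seed = 1L) {
  sides <- match.arg(sides)
  if (!(voxel_p > 0 && voxel_p < 1)) stop("voxel_p must be in (0, 1)")
  if (!(corrected_alpha > 0 && corrected_alpha < 1))
    stop("corrected_alpha must be in (0, 1)")
  if (n_iterations < 100) stop("n_iterations must be at least 100")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (fwhm_px < 0) stop("fwhm_px must be non-negative")
  structure(list(n_iterations = as.integer(n_iterations), voxel_p = voxel_p,
                 corrected_alpha = corrected_alpha, fwhm_px = fwhm_px,
                 connectivity = as.integer(connectivity), sides = sides,
                 positive_only = isTRUE(positive_only),
                 seed = as.integer(seed)),
            class = "bsm_mc_config")
}

#' Label connected suprathreshold components
#'
#' Maximal connected components of a binary map under 4- or
#' 8-connectivity, computed separately per body view (components never
#' span the front/back panel boundary). Labels are 1..K in order of
#' decreasing size; ties are broken by the component's first pixel in
#' row-major scan order.
#'
#' @param binary logical matrix (intersected with the template mask).
#' @param template a [body_template()].
#' @param connectivity 4 or 8.
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `sizes` (pixel count per label, decreasing).
#' @export
label_connected <- function(binary, template, connectivity = 8L) {
  stopifnot(inherits(template, "bsm_template"))
  binary <- (binary != 0) & template$mask
  domain <- matrix(0L, nrow(binary), ncol(binary))
  domain[binary] <- template$view_labels[binary]
  raw <- label_components_cpp(domain, as.integer(connectivity))
  k <- max(raw)
  if (k == 0L)
    return(list(labels = raw, sizes = integer(0)))
  sizes <- tabulate(raw, nbins = k)
  # row-major rank of each component's top-left-most pixel
  rm_rank <- (row(raw) - 1L) * ncol(raw) + col(raw)
  first <- vapply(seq_len(k), function(i) min(rm_rank[raw == i]), numeric(1))
  ord <- order(-sizes, first)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- raw
  labels[raw > 0L] <- relabel[raw[raw > 0L]]
  list(labels = labels, sizes = sizes[ord])
}

.null_threshold <- function(config) {
  if (config$sides == "two") qnorm(1 - config$voxel_p / 2)
  else qnorm(1 - config$voxel_p)
}

#' Simulate the null distribution of maximum cluster sizes
#'
#' The Monte-Carlo engine of the cluster-extent correction. Each
#' iteration draws an iid standard-normal field on the template canvas,
#' smooths it to `fwhm_px` ([smooth_map()], reflecting boundaries),
#' re-standardizes the in-mask values to zero mean and unit variance,
#' thresholds at the standard-normal quantile matching `voxel_p` (and the
#' configured sidedness), labels connected components per view, and
#' records the maximum component size (0 when no pixel survives). Fully
#' reproducible from `config$seed`.
#'
#' @param template a [body_template()].
#' @param config an [mc_config()].
#' @return object of class `bsm_null`: `max_sizes` (one per iteration),
#'   `config`, and a mask fingerprint.
#' @export
simulate_null_max_clusters <- function(template, config) {
  stopifnot(inherits(config, "bsm_mc_config"))
  h <- template$height; w <- template$width
  idx <- which(template$mask)
  viewvec <- template$view_labels[idx]
  thr <- .null_threshold(config)
  two <- config$sides == "two"
  sigma <- config$fwhm_px / (2 * sqrt(2 * log(2)))
  if (config$fwhm_px > 0) {
    Ar <- .blur_operator(h, sigma)
    Act <- t(.blur_operator(w, sigma))
  }
  dom0 <- matrix(0L, h, w)
  max_sizes <- integer(config$n_iterations)
  with_seed(config$seed, {
    for (i in seq_len(config$n_iterations)) {
      x <- matrix(rnorm(h * w), h, w)
      if (config$fwhm_px > 0) x <- Ar %*% x %*% Act
      v <- x[idx]
      v <- (v - mean(v)) / sd(v)
      sel <- if (two) abs(v) > thr else v > thr
      if (!any(sel)) next
      dom <- dom0
      dom[idx[sel]] <- viewvec[sel]
      lab <- label_components_cpp(dom, config$connectivity)
      max_sizes[i] <- max(tabulate(lab))
    }
  })
  structure(list(max_sizes = max_sizes, config = config,
                 mask_fingerprint = c(h, w, length(idx), sum(as.numeric(idx)))),
            class = "bsm_null")
}

#' @export
print.bsm_null <- function(x, ...) {
  cat(sprintf("<bsm_null> %d iterations, fwhm %.2f px, voxel p %.3g (%s-sided), max-size median %d, max %d\n",
              length(x$max_sizes), x$config$fwhm_px, x$config$voxel_p,
              x$config$sides, stats::median(x$max_sizes), max(x$max_sizes)))
  invisible(x)
}

#' Derive the cluster-extent threshold from a null distribution
#'
#' The smallest integer `k` such that the fraction of null iterations
#' whose maximum cluster size strictly exceeds `k` is at most
#' `corrected_alpha`. Significant clusters must therefore be strictly
#' larger than `k` pixels. When every iteration is empty the threshold is
#' 0 (achieved rate 0).
#'
#' @param null a `bsm_null` from [simulate_null_max_clusters()].
#' @param corrected_alpha target family-wise error rate; defaults to the
#'   value in the null's config.
#' @return list with `extent_threshold` (integer `k`), `achieved` (the
#'   null exceedance fraction at `k`) and `corrected_alpha`.
#' @export
cluster_threshold <- function(null, corrected_alpha = NULL) {
  stopifnot(inherits(null, "bsm_null"))
  alpha <- corrected_alpha %||% null$config$corrected_alpha
  sizes <- null$max_sizes
  n <- length(sizes)
  if (n == 0) stop("empty null distribution")
  kmax <- max(sizes)
  # exceed[k+1] = #{iterations with max size > k}, k = 0..kmax
  counts <- tabulate(sizes + 1L, nbins = kmax + 1L)   # counts of size k at k+1
  exceed <- n - cumsum(counts)
  k <- which(exceed / n <= alpha)[1] - 1L
  list(extent_threshold = as.integer(k), achieved = exceed[k + 1L] / n,
       corrected_alpha = alpha)
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Thresholds the map at `p < voxel_p` over valid pixels (restricted to
#' positive t when `positive_only`), labels connected components per
#' view, and marks as surviving those strictly larger than
#' `extent_threshold` pixels. Peak Z and its location are recorded per
#' cluster.
#'
#' @param stat a `bsm_stat` with `p` and `z` layers.
#' @param template a [body_template()].
#' @param config an [mc_config()].
#' @param extent_threshold integer extent cutoff `k` (clusters survive if
#'   size > k), e.g. from [cluster_threshold()].
#' @return object of class `bsm_cluster_set`: `labels`, `sizes`,
#'   `extent_threshold`, `surviving` (label ids), and a `table`
#'   data.frame (id, size, surviving, peak_z, peak_row, peak_col, view).
#' @export
extract_clusters <- function(stat, template, config, extent_threshold) {
  stopifnot(inherits(stat, "bsm_stat"))
  if (is.null(stat$p) || is.null(stat$z)) stop("stat map lacks p/z layers")
  k <- if (is.list(extent_threshold)) extent_threshold$extent_threshold else extent_threshold
  binary <- (stat$p < config$voxel_p) & stat$valid
  if (config$positive_only) binary <- binary & (stat$t > 0)
  lc <- label_connected(binary, template, config$connectivity)
  nclus <- length(lc$sizes)
  if (nclus == 0) {
    tab <- data.frame(id = integer(), size = integer(), surviving = logical(),
                      peak_z = numeric(), peak_row = integer(),
                      peak_col = integer(), view = character())
  } else {
    vn <- view_names(max(template$view_labels))
    rows <- lapply(seq_len(nclus), function(i) {
      in_i <- lc$labels == i
      zi <- stat$z[in_i]
      peak <- which(in_i, arr.ind = TRUE)[which.max(abs(zi)), , drop = TRUE]
      data.frame(id = i, size = lc$sizes[i],
                 surviving = lc$sizes[i] > k,
                 peak_z = zi[which.max(abs(zi))],
                 peak_row = unname(peak["row"]), peak_col = unname(peak["col"]),
                 view = vn[template$view_labels[peak["row"], peak["col"]]])
    })
    tab <- do.call(rbind, rows)
  }
  structure(list(labels = lc$labels, sizes = lc$sizes,
                 extent_threshold = as.integer(k),
                 surviving = tab$id[tab$surviving], table = tab),
            class = "bsm_cluster_set")
}

#' @export
print.bsm_cluster_set <- function(x, ...) {
  cat(sprintf("<bsm_cluster_set> %d cluster(s), %d surviving extent > %d px\n",
              length(x$sizes), length(x$surviving), x$extent_threshold))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Tabulate clusters with region annotations
#'
#' Extends the cluster table with the atlas region holding the largest
#' share of each cluster (see [region_report()]).
#'
#' @param clusters a `bsm_cluster_set`.
#' @param template a [body_template()] with a region atlas.
#' @return data.frame, one row per cluster.
#' @export
cluster_table <- function(clusters, template) {
  tab <- clusters$table
  if (!nrow(tab) || is.null(template$regions)) {
    tab$top_region <- character(nrow(tab))
    return(tab)
  }
  tab$top_region <- vapply(tab$id, function(i) {
    rep <- region_report(template, clusters$labels == i)
    if (nrow(rep)) rep$region[1] else ""
  }, character(1))
  tab
}

#' Persist / load a null distribution
#'
#' CSV with one maximum cluster size per line plus a JSON header carrying
#' the configuration and mask fingerprint.
#'
#' @param null a `bsm_null`.
#' @param path output path for the CSV (`.json` header written alongside).
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(null, path) {
  writeLines(as.character(null$max_sizes), path)
  hdr <- c(unclass(null$config), list(mask_fingerprint = null$mask_fingerprint))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_null_distribution
#' @export
read_null_distribution <- function(path) {
  sizes <- as.integer(readLines(path))
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fp <- hdr$mask_fingerprint
  hdr$mask_fingerprint <- NULL
  cfg <- do.call(mc_config, hdr)
  structure(list(max_sizes = sizes, config = cfg, mask_fingerprint = fp),
            class = "bsm_null")
}
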