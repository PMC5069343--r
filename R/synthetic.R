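#' Specify a planted sensation effect
#'
#' Describes one spatial effect a synthetic subject may draw: a Gaussian
#' blob around a center (e.g. a sensation at the stimulated point, or the
#' non-specific palm sensations present at baseline) or a constant-width
#' line along a waypoint path (a sensation propagating along a limb).
#'
#' @param kind `"blob"` or `"line"`.
#' @param center `(row, col)` center of a blob.
#' @param path k x 2 matrix of `(row, col)` waypoints of a line.
#' @param scale spatial scale in pixels (blob sigma / line half-width sigma).
#' @param amplitude mean marked intensity at the effect core.
#' @param prevalence probability that a given subject expresses the effect.
#' @param jitter sd (pixels) of the per-subject displacement of the effect.
#' @return object of class `bsm_effect`.
#' @export
effect_spec <- function(kind = c("blob", "line"), center = NULL, path = NULL,
                        scale = 3, amplitude = 1, prevalence = 1, jitter = 0) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  if (jitter < 0) stop("jitter must be non-negative")
  if (kind == "blob" && is.null(center)) stop("blob effects need a center")
  if (kind == "line") {
    if (is.null(path)) stop("line effects need a path")
    path <- as.matrix(path)
    if (ncol(path) != 2 || nrow(path) < 2) stop("path must be a k x 2 matrix, k >= 2")
  }
  structure(list(kind = kind, center = center, path = path, scale = scale,
                 amplitude = amplitude, prevalence = prevalence,
                 jitter = jitter),
            class = "bsm_effect")
}

# Deterministic intensity field of an effect displaced by `offset`
# (computed on a bounding box for speed, then placed on the canvas).
effect_field <- function(template, spec, offset = c(0, 0)) {
  h <- template$height; w <- template$width
  out <- matrix(0, h, w)
  s <- spec$scale
  if (spec$kind == "blob") {
    ctr <- spec$center + offset
    r0 <- max(1L, floor(ctr[1] - 4 * s)); r1 <- min(h, ceiling(ctr[1] + 4 * s))
    c0 <- max(1L, floor(ctr[2] - 4 * s)); c1 <- min(w, ceiling(ctr[2] + 4 * s))
    if (r0 > r1 || c0 > c1) return(out)
    d2 <- outer((r0:r1 - ctr[1])^2, (c0:c1 - ctr[2])^2, `+`)
    out[r0:r1, c0:c1] <- spec$amplitude * exp(-d2 / (2 * s^2))
  } else {
    path <- sweep(spec$path, 2, offset, `+`)
    pts <- .sample_polyline(path, step = 0.5)
    r0 <- max(1L, floor(min(pts[, 1]) - 4 * s)); r1 <- min(h, ceiling(max(pts[, 1]) + 4 * s))
    c0 <- max(1L, floor(min(pts[, 2]) - 4 * s)); c1 <- min(w, ceiling(max(pts[, 2]) + 4 * s))
    if (r0 > r1 || c0 > c1) return(out)
    rows <- r0:r1; cols <- c0:c1
    d2 <- matrix(Inf, length(rows), length(cols))
    for (p in seq_len(nrow(pts)))
      d2 <- pmin(d2, outer((rows - pts[p, 1])^2, (cols - pts[p, 2])^2, `+`))
    out[rows, cols] <- spec$amplitude * exp(-d2 / (2 * s^2))
  }
  out[!template$mask] <- 0
  out
}

.sample_polyline <- function(path, step = 0.5) {
  segs <- lapply(seq_len(nrow(path) - 1), function(i) {
    a <- path[i, ]; b <- path[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  })
  do.call(rbind, segs)
}

# Support of an effect: pixels at or above half its core amplitude.
effect_support <- function(template, spec) {
  effect_field(template, spec) >= spec$amplitude / 2
}

.anchor_in_mask <- function(template, spec, offset) {
  a <- if (spec$kind == "blob") spec$center else spec$path[1, ]
  a <- round(a + offset)
  a[1] >= 1 && a[1] <= template$height && a[2] >= 1 && a[2] <= template$width &&
    template$mask[a[1], a[2]]
}

#' Generate one synthetic subject drawing
#'
#' Each effect is expressed with probability `prevalence`, displaced by a
#' per-subject Gaussian jitter (re-drawn up to 10 times if it would leave
#' the body mask, then clipped to no displacement). Pixel noise is
#' additive Gaussian truncated at zero, and an optional lognormal
#' per-subject "marking gain" scales the whole drawing, mimicking
#' idiosyncratic drawing vigor (the unit-range normalization step is
#' expected to absorb it). Deterministic for a fixed `seed`.
#'
#' @param template a [body_template()].
#' @param effects list of [effect_spec()]s.
#' @param noise_sd sd of the truncated pixel noise, intensity units.
#' @param seed RNG seed (`NULL`: use the ambient RNG stream).
#' @param gain_sigma lognormal sigma of the per-subject gain (0 = off).
#' @param subject_id,session_kind,stimulus_type,stimulus_location session
#'   metadata, as in [sensation_map()].
#' @return a [sensation_map()].
#' @export
generate_subject_map <- function(template, effects = list(), noise_sd = 0.1,
                                 seed = NULL, gain_sigma = 0,
                                 subject_id = "S1", session_kind = "baseline",
                                 stimulus_type = NULL, stimulus_location = NULL) {
  with_seed(seed, {
    h <- template$height; w <- template$width
    signal <- matrix(0, h, w)
    for (spec in effects) {
      if (runif(1) > spec$prevalence) next
      offset <- c(0, 0)
      if (spec$jitter > 0) {
        ok <- FALSE
        for (try in 1:10) {
          offset <- round(rnorm(2, 0, spec$jitter))
          if (.anchor_in_mask(template, spec, offset)) { ok <- TRUE; break }
        }
        if (!ok) offset <- c(0, 0)   # clipped: fall back to the nominal site
      }
      signal <- signal + effect_field(template, spec, offset)
    }
    gain <- if (gain_sigma > 0) rlnorm(1, 0, gain_sigma) else 1
    noise <- if (noise_sd > 0) matrix(rnorm(h * w, 0, noise_sd), h, w) else 0
    values <- gain * pmax(signal + noise, 0)   # pmax(x, 0) keeps dims of x
    sensation_map(values, subject_id, session_kind, stimulus_type,
                  stimulus_location, template = template)
  })
}

#' Describe a synthetic study design
#'
#' Defaults mirror a typical body-mapping experiment: 25 subjects, one
#' baseline session plus 8 stimulation sessions (2 stimulus types x 4
#' locations), pixel noise sd 0.1 on unit-intensity drawings, lognormal
#' marking gain sigma 0.2.
#'
#' @param n_subjects number of subjects.
#' @param stimulus_types,locations condition factors (crossed).
#' @param effects named list (`"<type>:<location>"`) of lists of
#'   [effect_spec()]s planted in that condition's sessions.
#' @param baseline_effects effects present in every session including
#'   baseline (e.g. bilateral palm sensations), so that baseline
#'   subtraction can remove them.
#' @param noise_sd,gain_sigma noise model (see [generate_subject_map()]).
#' @param questionnaire_means optional 13 x 8 matrix of target cell means
#'   in \[0, 3\] (columns ordered as [intensity_matrix()]); scores are
#'   drawn per subject as Binomial(3, mean/3).
#' @return list of class `bsm_design`.
#' @export
study_design <- function(n_subjects = 25L,
                         stimulus_types = STIMULUS_TYPES,
                         locations = LOCATIONS,
                         effects = list(), baseline_effects = list(),
                         noise_sd = 0.1, gain_sigma = 0.2,
                         questionnaire_means = NULL) {
  structure(list(n_subjects = as.integer(n_subjects),
                 stimulus_types = stimulus_types, locations = locations,
                 effects = effects, baseline_effects = baseline_effects,
                 noise_sd = noise_sd, gain_sigma = gain_sigma,
                 questionnaire_means = questionnaire_means),
            class = "bsm_design")
}

#' Generate a complete synthetic study with ground truth
#'
#' One baseline map plus one map per condition for every subject;
#' baseline effects enter every session so baseline subtraction can
#' remove them. Ground truth records, per condition, the union of the
#' planted effect supports (pixels at or above half the core amplitude,
#' at the nominal unjittered location). Bit-reproducible from `seed`.
#'
#' @param template a [body_template()].
#' @param design a [study_design()].
#' @param seed RNG seed.
#' @return list with `dataset` (a [study_dataset()]) and `truth` (list
#'   with `masks`: named logical matrices per condition, and `effects`).
#' @export
generate_study <- function(template, design = study_design(), seed = 1L) {
  stopifnot(inherits(design, "bsm_design"))
  conds <- expand.grid(location = design$locations,
                       stimulus_type = design$stimulus_types,
                       stringsAsFactors = FALSE)[, c(2, 1)]
  ckeys <- paste(conds$stimulus_type, conds$location, sep = ":")
  truth_masks <- lapply(ckeys, function(k) {
    specs <- design$effects[[k]]
    m <- matrix(FALSE, template$height, template$width)
    for (s in specs) m <- m | effect_support(template, s)
    m
  })
  names(truth_masks) <- ckeys
  with_seed(seed, {
    maps <- list()
    qrows <- list()
    for (i in seq_len(design$n_subjects)) {
      sid <- sprintf("S%02d", i)
      maps[[length(maps) + 1L]] <- generate_subject_map(
        template, design$baseline_effects, design$noise_sd,
        gain_sigma = design$gain_sigma, subject_id = sid,
        session_kind = "baseline")
      for (j in seq_len(nrow(conds))) {
        specs <- c(design$baseline_effects, design$effects[[ckeys[j]]])
        maps[[length(maps) + 1L]] <- generate_subject_map(
          template, specs, design$noise_sd,
          gain_sigma = design$gain_sigma, subject_id = sid,
          session_kind = "stimulation",
          stimulus_type = conds$stimulus_type[j],
          stimulus_location = conds$location[j])
        if (!is.null(design$questionnaire_means)) {
          p <- pmin(1, pmax(0, design$questionnaire_means[, ckeys[j]] / 3))
          qrows[[length(qrows) + 1L]] <- data.frame(
            subject_id = sid, stimulus_type = conds$stimulus_type[j],
            stimulus_location = conds$location[j],
            item = seq_len(N_ITEMS), score = rbinom(N_ITEMS, 3, p))
        }
      }
    }
    qdf <- if (length(qrows)) do.call(rbind, qrows)
    ds <- study_dataset(template, maps, qdf, provenance = "synthetic")
    list(dataset = ds,
         truth = list(masks = truth_masks, effects = design$effects,
                      baseline_effects = design$baseline_effects))
  })
}

#' Generate a null study (no planted effects)
#'
#' Pure-noise drawings: the ground truth is empty everywhere. Used to
#' measure empirical family-wise error of the corrected pipeline.
#'
#' @inheritParams generate_study
#' @param n_subjects number of subjects.
#' @param noise_sd truncated pixel-noise sd.
#' @param conditions data.frame with `stimulus_type`/`location` columns,
#'   default a single acupuncture:HT7 condition.
#' @return a [study_dataset()] (baseline + conditions per subject).
#' @export
generate_null_study <- function(template, n_subjects = 25L, noise_sd = 0.1,
                                seed = 1L,
                                conditions = data.frame(
                                  stimulus_type = "acupuncture",
                                  location = "HT7")) {
  design <- study_design(n_subjects = n_subjects,
                         stimulus_types = unique(conditions$stimulus_type),
                         locations = unique(conditions$location),
                         noise_sd = noise_sd, gain_sigma = 0)
  generate_study(template, design, seed)$dataset
}

#' Assemble per-subject analysis stacks for one condition
#'
#' The glue between a dataset and the pixel statistics: for every subject
#' with the requested session, returns the normalized map (or, with
#' `baseline_correct`, the normalized map minus the subject's normalized
#' baseline). Errors name the subject if a needed baseline is missing.
#'
#' @param dataset a [study_dataset()].
#' @param stimulus_type,location condition selector.
#' @param baseline_correct subtract the subject baseline.
#' @param normalize apply [normalize_unit_range()] (default TRUE).
#' @return list of `bsm_map` / `bsm_diff` objects, one per subject.
#' @export
condition_stack <- function(dataset, stimulus_type, location,
                            baseline_correct = FALSE, normalize = TRUE) {
  key <- paste(stimulus_type, location, sep = ":")
  out <- list()
  for (sid in study_subjects(dataset)) {
    m <- get_map(dataset, sid, key)
    if (is.null(m)) next
    if (normalize) m <- suppressWarnings(normalize_unit_range(m))
    if (baseline_correct) {
      b <- get_map(dataset, sid, "baseline")
      if (is.null(b)) stop("subject ", sid, " has no baseline session")
      if (normalize) b <- suppressWarnings(normalize_unit_range(b))
      m <- subtract_baseline(m, b)
    }
    out[[sid]] <- m
  }
  out
}

#' Empirical family-wise error of the corrected pipeline
#'
#' Repeats the full null analysis many times: simulate a null study
#' (baseline + one stimulation session per subject, truncated-noise
#' drawings), normalize, subtract baseline, compute the pixel-wise
#' one-sample t-map on the differences, extract clusters at the
#' configured voxel threshold, and record whether any cluster strictly
#' exceeds the extent threshold. The returned rate estimates the
#' family-wise type-I error of the procedure.
#'
#' @param template a [body_template()].
#' @param extent_threshold extent cutoff `k` (or a [cluster_threshold()]
#'   result).
#' @param config an [mc_config()] (voxel_p / connectivity / positive_only
#'   are used).
#' @param n_studies number of simulated null studies.
#' @param n_subjects subjects per study.
#' @param noise_sd truncated pixel-noise sd.
#' @param seed RNG seed.
#' @return list: `fwe` (fraction of studies with a surviving cluster),
#'   `n_studies`, `n_false` and the binomial standard error `se`.
#' @export
empirical_fwe <- function(template, extent_threshold, config,
                          n_studies = 1000L, n_subjects = 25L,
                          noise_sd = 1, seed = 1L) {
  k <- if (is.list(extent_threshold)) extent_threshold$extent_threshold else extent_threshold
  idx <- which(template$mask)
  npix <- length(idx)
  viewvec <- template$view_labels[idx]
  dom0 <- matrix(0L, template$height, template$width)
  tcrit <- if (config$sides == "two") qt(1 - config$voxel_p / 2, n_subjects - 1)
           else qt(1 - config$voxel_p, n_subjects - 1)
  n_false <- 0L
  with_seed(seed, {
    for (s in seq_len(n_studies)) {
      base <- matrix(pmax(0, rnorm(n_subjects * npix, 0, noise_sd)), n_subjects)
      stim <- matrix(pmax(0, rnorm(n_subjects * npix, 0, noise_sd)), n_subjects)
      base <- base / apply(base, 1, max)       # unit-range normalization
      stim <- stim / apply(stim, 1, max)
      core <- .tmap_core(stim - base)
      sel <- core$valid & (core$t > tcrit)     # positive suprathreshold pixels
      if (!config$positive_only) sel <- sel | (core$valid & core$t < -tcrit)
      if (!any(sel)) next
      dom <- dom0
      dom[idx[sel]] <- viewvec[sel]
      lab <- label_components_cpp(dom, config$connectivity)
      if (max(tabulate(lab)) > k) n_false <- n_false + 1L
    }
  })
  a <- config$corrected_alpha
  list(fwe = n_false / n_studies, n_studies = n_studies, n_false = n_false,
       se = sqrt(a * (1 - a) / n_studies))
}
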