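#' Normalize a sensation map to unit range
#'
#' Divides by the in-mask maximum, so values span \[0, 1\] with unmarked
#' (zero) pixels staying at zero and the maximum exactly 1. The operation
#' is idempotent and scale-invariant. An all-zero map is returned
#' unchanged with a warning (there is nothing to scale).
#'
#' @param map a [sensation_map()] or a plain non-negative matrix.
#' @return object of the same kind, with the `normalized` flag set.
#' @export
normalize_unit_range <- function(map) {
  if (is.matrix(map)) {
    mx <- max(map)
    if (mx == 0) {
      warning("all-zero map: nothing to normalize")
      return(map)
    }
    return(map / mx)
  }
  stopifnot(inherits(map, "bsm_map"))
  mx <- max(map$values)
  if (mx == 0) {
    warning("all-zero map (subject ", map$subject_id, "): nothing to normalize")
  } else {
    map$values <- map$values / mx
  }
  map$normalized <- TRUE
  map
}

#' Subtract a baseline map from a stimulation map
#'
#' Pixel-wise `stim - base` of two unit-range-normalized maps of the same
#' subject. Negative values are retained: the signed difference preserves
#' where baseline sensations (e.g. the palms) exceeded the stimulation
#' drawing; one-sided selection happens later at cluster extraction.
#'
#' @param stim,base normalized [sensation_map()] objects, same subject and shape.
#' @return object of class `bsm_diff` with fields `values` (signed matrix),
#'   `subject_id` and the stimulation session metadata.
#' @export
subtract_baseline <- function(stim, base) {
  stopifnot(inherits(stim, "bsm_map"), inherits(base, "bsm_map"))
  if (!identical(stim$subject_id, base$subject_id))
    stop("maps are from different subjects (", stim$subject_id, " vs ",
         base$subject_id, ")")
  if (!stim$normalized || !base$normalized)
    stop("subtract_baseline requires normalized inputs")
  if (!identical(dim(stim$values), dim(base$values))) stop("shape mismatch")
  structure(list(values = stim$values - base$values,
                 subject_id = stim$subject_id,
                 stimulus_type = stim$stimulus_type,
                 stimulus_location = stim$stimulus_location),
            class = "bsm_diff")
}

# Cached 1D reflect-boundary Gaussian convolution operators. Smoothing a
# matrix is then two small matrix products (rows, columns), exact at the
# boundary under reflection and fast enough for 10k-iteration null
# simulations.
.blur_cache <- new.env(parent = emptyenv())

.reflect_idx <- function(i, n) {
  # scipy-style "reflect": (d c b a | a b c d | d c b a)
  while (any(bad <- (i < 1L | i > n))) {
    i[i < 1L] <- 1L - i[i < 1L]
    i[i > n] <- 2L * n + 1L - i[i > n]
  }
  i
}

.blur_operator <- function(n, sigma) {
  key <- sprintf("%d_%.10g", n, sigma)
  op <- .blur_cache[[key]]
  if (!is.null(op)) return(op)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  A <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- .reflect_idx(seq_len(n) + o, n)
    A[cbind(seq_len(n), idx)] <- A[cbind(seq_len(n), idx)] + k[o + r + 1L]
  }
  .blur_cache[[key]] <- A
  A
}

#' Smooth a map with a Gaussian kernel
#'
#' Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))`, computed
#' on the full canvas with reflecting boundaries (avoiding edge dimming
#' inside the body) and then re-masked when a template is supplied.
#' `fwhm = 0` is the identity.
#'
#' @param x numeric matrix.
#' @param fwhm full width at half maximum of the kernel, in pixels.
#' @param template optional [body_template()]; output is zeroed outside
#'   its mask.
#' @return smoothed matrix.
#' @export
smooth_map <- function(x, fwhm, template = NULL) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  stopifnot(is.matrix(x))
  if (fwhm > 0) {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    Ar <- .blur_operator(nrow(x), sigma)
    Ac <- .blur_operator(ncol(x), sigma)
    x <- Ar %*% x %*% t(Ac)
  }
  if (!is.null(template)) x[!template$mask] <- 0
  x
}

#' Estimate the smoothness (FWHM) of residual maps
#'
#' Variance-of-first-differences estimator: for a Gaussian-smoothed white
#' field, neighbouring-pixel correlation is `1 - var(dX) / (2 var(X))`,
#' which inverts to the kernel sigma and hence FWHM. Applied to the
#' mean-removed subject maps (residuals) in each in-mask direction and
#' averaged; returns 0 when neighbours are uncorrelated. Used as the
#' default smoothness of simulated null fields, which a Monte-Carlo
#' cluster-extent calibration needs but drawings do not carry explicitly.
#'
#' @param stack list of matrices (or objects with a `values` field), one
#'   per subject.
#' @param template a [body_template()].
#' @return estimated FWHM in pixels (a single number).
#' @export
estimate_fwhm <- function(stack, template) {
  mats <- lapply(stack, function(m) if (is.matrix(m)) m else m$values)
  mean_map <- Reduce(`+`, mats) / length(mats)
  mask <- template$mask
  h <- nrow(mask); w <- ncol(mask)
  pair_h <- mask[, -w] & mask[, -1]   # horizontal neighbour pairs
  pair_v <- mask[-h, ] & mask[-1, ]   # vertical neighbour pairs
  num_h <- den <- num_v <- 0
  for (m in mats) {
    r <- m - mean_map
    den <- den + sum(r[mask]^2)
    dh <- r[, -1] - r[, -w]
    dv <- r[-1, ] - r[-h, ]
    num_h <- num_h + sum(dh[pair_h]^2)
    num_v <- num_v + sum(dv[pair_v]^2)
  }
  den <- den / (length(mats) * sum(mask))
  if (den == 0) return(0)
  fw <- vapply(c(num_h / (length(mats) * sum(pair_h)),
                 num_v / (length(mats) * sum(pair_v))), function(s2) {
    ratio <- s2 / (2 * den)
    if (ratio >= 1) return(0)   # uncorrelated or anticorrelated: no smoothness
    sig2 <- -1 / (4 * log(1 - ratio))
    2 * sqrt(2 * log(2)) * sqrt(sig2)
  }, numeric(1))
  mean(fw)
}
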