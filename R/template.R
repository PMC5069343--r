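#' Construct a body template
#'
#' A `bsm_template` defines the spatial domain of all analyses: a binary
#' body-silhouette mask, a partition of the mask into front and back views
#' laid out side by side on one canvas, and an optional named region atlas
#' used to report where clusters fall. The two views are treated as
#' separate connected domains: clusters never span the panel gap, since
#' adjacency across the layout boundary is an artifact of the canvas, not
#' anatomy.
#'
#' @param mask logical (or 0/1) matrix, `TRUE` inside the body.
#' @param view_labels integer matrix, 0 = outside, 1 = front view,
#'   2 = back view. Defaults to a single view covering the mask.
#' @param regions optional named list of logical matrices (subsets of the
#'   mask) naming anatomical regions.
#' @param outline optional numeric raster used for rendering.
#' @return An object of class `bsm_template` with fields `width`, `height`,
#'   `mask`, `view_labels`, `regions`, `outline`.
#' @export
body_template <- function(mask, view_labels = NULL, regions = NULL,
                          outline = NULL) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  if (is.null(view_labels)) {
    view_labels <- matrix(0L, nrow(mask), ncol(mask))
    view_labels[mask] <- 1L
  }
  if (!identical(dim(view_labels), dim(mask)))
    stop("view_labels dimensions do not match mask")
  storage.mode(view_labels) <- "integer"
  if (!identical(unname(view_labels > 0L), unname(mask)))
    stop("view_labels must be nonzero exactly on the mask")
  if (!is.null(regions)) {
    nm <- names(regions)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      stop("regions must be a uniquely named list")
    for (r in regions) {
      if (!identical(dim(r), dim(mask)))
        stop("region mask dimensions do not match mask")
      if (any((r != 0) & !mask)) stop("region masks must be subsets of the mask")
    }
    regions <- lapply(regions, function(r) r != 0)
  }
  structure(list(width = ncol(mask), height = nrow(mask), mask = mask,
                 view_labels = view_labels, regions = regions,
                 outline = outline),
            class = "bsm_template")
}

#' @export
print.bsm_template <- function(x, ...) {
  cat(sprintf("<bsm_template> %dx%d canvas, %d mask pixels, %d view(s), %d region(s)\n",
              x$height, x$width, sum(x$mask),
              length(unique(x$view_labels[x$mask])),
              length(x$regions)))
  invisible(x)
}

view_names <- function(n_views) if (n_views == 1L) "front" else c("front", "back")

# integer pixel range for a [lo, hi] fraction of an n-pixel axis
.frac_range <- function(lo, hi, n) {
  a <- max(1L, round(lo * n))
  b <- min(n, round(hi * n))
  if (b < a) a
  else a:b
}

.panel_cols <- function(width, n_views, v) {
  wp <- width %/% n_views
  ((v - 1L) * wp + 1L):(v * wp)
}

# Per-panel humanoid silhouette: head, neck, torso (chest/abdomen), two
# arms ending in hands, two legs. Boundaries are computed sequentially and
# the right-side limbs mirror the left, so regions are disjoint and
# nonempty at any panel size from 8x16 up; limbs are wide enough to carry
# line-like effects. The neck belongs to the mask but to no region.
.humanoid_panel <- function(h, wp) {
  shp <- function() matrix(FALSE, h, wp)
  mirror <- function(cols) sort(wp + 1L - cols)
  rg <- list()
  # row bands
  chest_r0 <- round(0.24 * h); chest_r1 <- round(0.40 * h)
  abd_r1 <- round(0.58 * h)
  arm_r0 <- round(0.26 * h); arm_r1 <- round(0.52 * h)
  hand_r1 <- round(0.60 * h)
  leg_r1 <- round(0.95 * h)
  # column bands (left side; right side mirrored)
  la_cols <- max(1L, round(0.18 * wp)):round(0.30 * wp)
  t0 <- max(max(la_cols) + 1L, round(0.33 * wp))
  torso_cols <- t0:(wp + 1L - t0)
  ll_cols <- max(t0, round(0.36 * wp)):min(wp %/% 2L, round(0.48 * wp))
  head <- shp()
  hr <- max(2, 0.09 * min(h, wp)); hc <- 0.12 * h; cc <- (wp + 1) / 2
  for (j in seq_len(wp)) {
    rows <- which((seq_len(h) - hc)^2 + (j - cc)^2 <= hr^2)
    head[rows, j] <- TRUE
  }
  rg$head <- head
  chest <- shp(); chest[chest_r0:chest_r1, torso_cols] <- TRUE
  abdomen <- shp(); abdomen[(chest_r1 + 1L):abd_r1, torso_cols] <- TRUE
  rg$chest <- chest; rg$abdomen <- abdomen
  la <- shp(); la[arm_r0:arm_r1, la_cols] <- TRUE
  ra <- shp(); ra[arm_r0:arm_r1, mirror(la_cols)] <- TRUE
  lh <- shp(); lh[(arm_r1 + 1L):hand_r1, la_cols] <- TRUE
  rh <- shp(); rh[(arm_r1 + 1L):hand_r1, mirror(la_cols)] <- TRUE
  rg$left_arm <- la; rg$right_arm <- ra
  rg$left_hand <- lh; rg$right_hand <- rh
  ll <- shp(); ll[(abd_r1 + 1L):leg_r1, ll_cols] <- TRUE
  rl <- shp(); rl[(abd_r1 + 1L):leg_r1, mirror(ll_cols)] <- TRUE
  rg$left_leg <- ll; rg$right_leg <- rl
  neck <- shp()
  neck[max(1L, round(0.13 * h)):(chest_r0 - 1L),
       .frac_range(0.45, 0.55, wp)] <- TRUE
  ov <- Reduce(`+`, rg)
  if (max(ov) > 1) stop("internal error: humanoid regions overlap")
  if (any(vapply(rg, sum, numeric(1)) == 0))
    stop("internal error: empty humanoid region")
  list(mask = (ov + neck) > 0, regions = rg)
}

#' Generate a synthetic body template
#'
#' Deterministic test-and-simulation templates. Style `"rectangle"` fills a
#' centered rectangle occupying about half of each view panel; style
#' `"humanoid"` draws a stylized body (head, chest, abdomen, arms, hands,
#' legs per view) with a matching named region atlas, so that blob-like and
#' line-like (limb-following) effects are representable.
#'
#' @param width,height canvas size in pixels (each at least 16).
#' @param style `"humanoid"` or `"rectangle"`.
#' @param n_views number of side-by-side view panels (1 or 2).
#' @return A [body_template()].
#' @export
make_synthetic_template <- function(width, height,
                                    style = c("humanoid", "rectangle"),
                                    n_views = 2L) {
  style <- match.arg(style)
  n_views <- as.integer(n_views)
  if (width < 16 || height < 16) stop("template dimensions too small (minimum 16)")
  if (!n_views %in% c(1L, 2L)) stop("n_views must be 1 or 2")
  wp <- width %/% n_views
  mask <- matrix(FALSE, height, width)
  views <- matrix(0L, height, width)
  regions <- list()
  vn <- view_names(n_views)
  for (v in seq_len(n_views)) {
    cols <- .panel_cols(width, n_views, v)
    if (style == "rectangle") {
      rh <- round(height / sqrt(2)); rw <- round(wp / sqrt(2))
      r0 <- (height - rh) %/% 2L; c0 <- (wp - rw) %/% 2L
      pm <- matrix(FALSE, height, wp)
      pm[(r0 + 1L):(r0 + rh), (c0 + 1L):(c0 + rw)] <- TRUE
      prg <- list(body = pm)
    } else {
      hp <- .humanoid_panel(height, wp)
      pm <- hp$mask
      prg <- hp$regions
    }
    mask[, cols] <- pm
    vv <- views[, cols]; vv[pm] <- v; views[, cols] <- vv
    for (nm in names(prg)) {
      full <- matrix(FALSE, height, width)
      full[, cols] <- prg[[nm]]
      regions[[paste(vn[v], nm, sep = "_")]] <- full
    }
  }
  body_template(mask, views, regions)
}

#' Load a body template
#'
#' `source` is either the name of a packaged template or the path to a
#' grayscale PNG silhouette. Any nonzero pixel is inside the body (so
#' anti-aliased silhouettes are tolerated). Unless a sidecar YAML supplies
#' an explicit view map, the left half of the canvas is the front view and
#' the right half the back view. The builtin `"default-1024"` is a
#' synthetic humanoid silhouette on a 1024x1024 canvas; it approximates
#' the layout of typical body-drawing templates and is not claimed to
#' match any specific published template pixel for pixel.
#'
#' @param source builtin name (`"default-1024"`) or PNG file path.
#' @param sidecar optional YAML path with keys `views` (PNG of 0/1/2 view
#'   codes) and `regions` (list of `png` path to an indexed-value PNG and
#'   `names`, mapping pixel value to region name). Paths are relative to
#'   the sidecar file.
#' @return A [body_template()].
#' @export
load_template <- function(source, sidecar = NULL) {
  if (identical(source, "default-1024"))
    return(make_synthetic_template(1024, 1024, "humanoid", n_views = 2L))
  if (!file.exists(source)) stop("unreadable template file: ", source)
  img <- .read_gray_png(source)
  mask <- img > 0
  if (!any(mask)) stop("empty mask")
  h <- nrow(mask); w <- ncol(mask)
  views <- NULL; regions <- NULL
  if (!is.null(sidecar)) {
    sc <- yaml::read_yaml(sidecar)
    base <- dirname(sidecar)
    if (!is.null(sc$views)) {
      vm <- .read_gray_png(file.path(base, sc$views))
      if (!identical(dim(vm), dim(mask)))
        stop("view map dimensions do not match template")
      views <- matrix(as.integer(round(vm * 255)), h, w)
      views[!mask] <- 0L
    }
    if (!is.null(sc$regions)) {
      rm_ <- .read_gray_png(file.path(base, sc$regions$png))
      if (!identical(dim(rm_), dim(mask)))
        stop("region map dimensions do not match template")
      idx <- matrix(as.integer(round(rm_ * 255)), h, w)
      regions <- lapply(sc$regions$names, function(code) idx == code)
      names(regions) <- names(sc$regions$names)
      regions <- lapply(regions, function(r) r & mask)
    }
  }
  if (is.null(views)) {
    views <- matrix(0L, h, w)
    half <- w %/% 2L
    views[mask] <- ifelse(col(mask)[mask] <= half, 1L, 2L)
  }
  body_template(mask, views, regions, outline = img)
}

.read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3 &&
        all(img[, , 1] == img[, , 2]) && all(img[, , 1] == img[, , 3]))
      img <- img[, , 1]
    else stop("multi-channel PNG not supported; provide a grayscale image")
  }
  img
}

#' Report where a cluster falls on the region atlas
#'
#' For a binary cluster mask inside the template, returns the fraction of
#' cluster pixels falling in each named region (descending), with pixels
#' outside every named region reported as `"unassigned"`. Fractions sum to
#' 1 for a nonempty cluster (the atlas regions are disjoint).
#'
#' @param template a [body_template()].
#' @param cluster logical matrix, subset of the template mask.
#' @return data.frame with columns `region`, `pixels`, `fraction`.
#' @export
region_report <- function(template, cluster) {
  stopifnot(inherits(template, "bsm_template"))
  cluster <- cluster != 0
  if (!identical(dim(cluster), dim(template$mask)))
    stop("cluster dimensions do not match template")
  if (any(cluster & !template$mask)) stop("cluster not inside mask")
  total <- sum(cluster)
  if (total == 0)
    return(data.frame(region = character(), pixels = integer(),
                      fraction = numeric()))
  counts <- vapply(template$regions, function(r) sum(cluster & r), integer(1))
  un <- total - sum(counts)
  if (un > 0) counts <- c(counts, unassigned = un)
  counts <- counts[counts > 0]
  out <- data.frame(region = names(counts), pixels = as.integer(counts),
                    fraction = as.numeric(counts) / total,
                    row.names = NULL)
  out[order(-out$fraction, out$region), , drop = FALSE]
}
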