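test_that("connectivity semantics: diagonal pixels touch only under 8-connectivity", {
  tpl <- full_template(6)
  b <- matrix(FALSE, 6, 6); b[2, 2] <- b[3, 3] <- TRUE
  l4 <- label_connected(b, tpl, 4)
  expect_equal(l4$sizes, c(1L, 1L))
  l8 <- label_connected(b, tpl, 8)
  expect_equal(l8$sizes, 2L)
  empty <- label_connected(matrix(FALSE, 6, 6), tpl, 8)
  expect_equal(length(empty$sizes), 0)
})

test_that("clusters never span the front/back view boundary", {
  tpl <- make_synthetic_template(16, 16, "rectangle", n_views = 2)
  b <- tpl$mask        # a band crossing both panels
  lc <- label_connected(b, tpl, 8)
  expect_equal(length(lc$sizes), 2)
  v1 <- unique(tpl$view_labels[lc$labels == 1])
  v2 <- unique(tpl$view_labels[lc$labels == 2])
  expect_equal(length(v1), 1)
  expect_equal(length(v2), 1)
  expect_false(v1 == v2)
})

test_that("labeling matches the flood-fill oracle on random grids", {
  tpl <- full_template(12)
  set.seed(101)
  for (rep in 1:60) {
    b <- matrix(runif(144) < 0.4, 12, 12)
    for (conn in c(4, 8)) {
      got <- label_connected(b, tpl, conn)
      ora <- flood_fill_label(b, conn)
      expect_identical(got$labels, ora$labels)
      expect_identical(got$sizes, as.integer(ora$sizes))
    }
  }
})

test_that("label ordering is by size, ties broken in row-major scan order", {
  tpl <- full_template(8)
  b <- matrix(FALSE, 8, 8)
  b[6, 1:3] <- TRUE                 # size 3
  b[1, 6:7] <- TRUE                 # size 2, appears first in row-major order
  b[4, 5:6] <- TRUE                 # size 2
  lc <- label_connected(b, tpl, 8)
  expect_equal(lc$sizes, c(3L, 2L, 2L))
  expect_equal(unique(lc$labels[6, 1:3]), 1L)
  expect_equal(unique(lc$labels[1, 6:7]), 2L)   # row-major-first tie winner
  expect_equal(unique(lc$labels[4, 5:6]), 3L)
})

test_that("null simulation is reproducible and has the nominal pixel rate", {
  tpl <- full_template(10)
  cfg <- mc_config(n_iterations = 400, voxel_p = 0.05, fwhm_px = 0, seed = 77)
  n1 <- simulate_null_max_clusters(tpl, cfg)
  n2 <- simulate_null_max_clusters(tpl, cfg)
  expect_identical(n1$max_sizes, n2$max_sizes)

  # unsmoothed two-sided thresholding marks ~ voxel_p of the 100 pixels
  set.seed(1)
  counts <- replicate(400, {
    v <- rnorm(100); v <- (v - mean(v)) / sd(v)
    sum(abs(v) > qnorm(0.975))
  })
  expect_equal(mean(counts), 5, tolerance = 0.5)   # binomial expectation
})

test_that("extent threshold is the smallest k with exceedance <= alpha", {
  mk_null <- function(sizes) structure(
    list(max_sizes = sizes,
         config = mc_config(n_iterations = 100, corrected_alpha = 0.25, seed = 1)),
    class = "bsm_null")
  thr <- cluster_threshold(mk_null(c(1L, 1L, 1L, 10L)), 0.25)
  expect_equal(thr$extent_threshold, 1L)           # exceeded in 1/4 of iterations
  expect_equal(thr$achieved, 0.25)
  thr0 <- cluster_threshold(mk_null(rep(0L, 50)), 0.05)
  expect_equal(thr0$extent_threshold, 0L)
  expect_equal(thr0$achieved, 0)
})

test_that("extent threshold is monotone in voxel_p and fwhm", {
  tpl <- full_template(32)
  ks <- vapply(c(0.10, 0.05, 0.01), function(p) {
    cfg <- mc_config(n_iterations = 600, voxel_p = p, fwhm_px = 3, seed = 5)
    cluster_threshold(simulate_null_max_clusters(tpl, cfg))$extent_threshold
  }, integer(1))
  expect_true(all(diff(ks) <= 0))                  # stricter voxel p, smaller k
  kf <- vapply(c(0, 3, 6), function(fw) {
    cfg <- mc_config(n_iterations = 600, voxel_p = 0.05, fwhm_px = fw, seed = 5)
    cluster_threshold(simulate_null_max_clusters(tpl, cfg))$extent_threshold
  }, integer(1))
  expect_true(all(diff(kf) >= 0))                  # smoother nulls, larger k
})

test_that("cluster extraction applies a strict extent inequality", {
  tpl <- full_template(12)
  set.seed(41)
  # signal + noise only inside a 2x3 blob; elsewhere zero variance, so the
  # suprathreshold set is exactly the blob
  stack <- lapply(1:12, function(i) {
    m <- matrix(0, 12, 12)
    m[4:5, 4:6] <- 2 + rnorm(6, 0, 0.1)
    m
  })
  st <- one_sample_tmap(stack, tpl)
  cfg <- mc_config(n_iterations = 100, voxel_p = 0.05, seed = 1)
  cl4 <- extract_clusters(st, tpl, cfg, 5)         # blob of 6 pixels: survives
  expect_true(1 %in% cl4$surviving)
  expect_equal(max(cl4$sizes), 6L)
  cl5 <- extract_clusters(st, tpl, cfg, 6)         # equal size does not survive
  expect_false(1 %in% cl5$surviving)
  expect_equal(cl4$table$peak_row[1], which.max(apply(abs(st$z), 1, max)))

  # a map with nothing below voxel_p gives an empty cluster set
  null_stack <- lapply(1:12, function(i) matrix(1 + rnorm(144, 0, 1e-3), 12))
  st0 <- one_sample_tmap(null_stack, tpl)
  st0$p[] <- 1
  cl0 <- extract_clusters(st0, tpl, cfg, 0)
  expect_equal(length(cl0$sizes), 0)
  expect_equal(nrow(cl0$table), 0)
})

test_that("positive-only extraction ignores negative clusters", {
  tpl <- full_template(12)
  set.seed(42)
  stack <- lapply(1:12, function(i) {
    m <- matrix(0, 12, 12)
    m[8:9, 8:10] <- -2 + rnorm(6, 0, 0.1)   # purely negative effect
    m
  })
  st <- one_sample_tmap(stack, tpl)
  cfg_pos <- mc_config(n_iterations = 100, voxel_p = 0.05, seed = 1)
  expect_equal(length(extract_clusters(st, tpl, cfg_pos, 0)$sizes), 0)
  cfg_two <- mc_config(n_iterations = 100, voxel_p = 0.05, seed = 1,
                       positive_only = FALSE)
  cl <- extract_clusters(st, tpl, cfg_two, 0)
  expect_gte(max(cl$sizes), 6)
  expect_lt(cl$table$peak_z[1], 0)
})

test_that("null distributions persist to CSV + JSON and read back", {
  tpl <- full_template(10)
  cfg <- mc_config(n_iterations = 150, fwhm_px = 2, seed = 3)
  nd <- simulate_null_max_clusters(tpl, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_null_distribution(nd, path)
  nd2 <- read_null_distribution(path)
  expect_identical(nd2$max_sizes, nd$max_sizes)
  expect_equal(nd2$config$fwhm_px, cfg$fwhm_px)
  expect_equal(nd2$mask_fingerprint, nd$mask_fingerprint)
  expect_equal(cluster_threshold(nd2), cluster_threshold(nd))
})
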