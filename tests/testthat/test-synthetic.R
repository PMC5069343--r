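tpl64 <- make_synthetic_template(64, 64, "humanoid")

test_that("subject map generation is deterministic and respects degenerate settings", {
  m1 <- generate_subject_map(tpl64, list(), noise_sd = 0, seed = 1)
  expect_equal(max(m1$values), 0)                      # no effects, no noise

  blob <- effect_spec("blob", center = c(30, 16), scale = 3, amplitude = 1)
  m2 <- generate_subject_map(tpl64, list(blob), noise_sd = 0, seed = 1)
  expect_equal(which(m2$values == max(m2$values)),
               which(row(m2$values) == 30 & col(m2$values) == 16))
  expect_equal(max(m2$values), 1)

  m3a <- generate_subject_map(tpl64, list(blob), noise_sd = 0.1, seed = 9)
  m3b <- generate_subject_map(tpl64, list(blob), noise_sd = 0.1, seed = 9)
  expect_identical(m3a$values, m3b$values)
  m3c <- generate_subject_map(tpl64, list(blob), noise_sd = 0.1, seed = 10)
  expect_false(identical(m3a$values, m3c$values))
  expect_true(all(m3a$values >= 0))
  expect_true(all(m3a$values[!tpl64$mask] == 0))
})

test_that("line effects trace the dilated waypoint path", {
  leg <- which(tpl64$regions$front_left_leg, arr.ind = TRUE)
  path <- rbind(leg[which.min(leg[, 1]), ], leg[which.max(leg[, 1]), ])
  spec <- effect_spec("line", path = path, scale = 2, amplitude = 1)
  fld <- bsmap:::effect_field(tpl64, spec)
  sup <- fld >= 0.5
  # independent reconstruction: pixels within the half-max distance of the
  # densely sampled segment (within the mask)
  pts <- bsmap:::.sample_polyline(path, 0.5)
  d2min <- matrix(Inf, 64, 64)
  for (p in seq_len(nrow(pts)))
    d2min <- pmin(d2min, (row(d2min) - pts[p, 1])^2 + (col(d2min) - pts[p, 2])^2)
  sup_oracle <- (exp(-d2min / (2 * 4)) >= 0.5) & tpl64$mask
  expect_identical(sup, sup_oracle)
  expect_gt(sum(sup), 0)
})

test_that("study generation produces the full session grid with ground truth", {
  tpl <- make_synthetic_template(32, 32, "rectangle")
  # default-sized design: 25 subjects x (1 baseline + 8 sessions)
  des <- study_design(n_subjects = 25, noise_sd = 0.05, gain_sigma = 0)
  gs <- generate_study(tpl, des, seed = 11)
  expect_equal(length(gs$dataset$maps), 25 * 9)
  expect_equal(length(study_subjects(gs$dataset)), 25)
  expect_equal(sort(names(gs$truth$masks)),
               sort(paste(rep(c("acupuncture", "tactile"), each = 4),
                          c("HT7", "PC6", "ST36", "SP10"), sep = ":")))
  expect_true(all(!vapply(gs$truth$masks, any, logical(1))))  # no planted effects

  # small design: n=4, one condition, no effects -> 8 maps
  des2 <- study_design(n_subjects = 4, stimulus_types = "acupuncture",
                       locations = "HT7", noise_sd = 0.05)
  gs2 <- generate_study(make_synthetic_template(16, 16, "rectangle"), des2, seed = 2)
  expect_equal(length(gs2$dataset$maps), 8)

  gs3 <- generate_study(make_synthetic_template(16, 16, "rectangle"), des2, seed = 2)
  expect_identical(gs2$dataset$maps, gs3$dataset$maps)        # bit-identical
})

test_that("baseline effects appear in every session and cancel after subtraction", {
  tpl <- make_synthetic_template(48, 48, "humanoid")
  palmL <- which(tpl$regions$front_left_hand, arr.ind = TRUE)[1, ]
  palm <- effect_spec("blob", center = palmL, scale = 2, amplitude = 1)
  des <- study_design(n_subjects = 6, stimulus_types = "acupuncture",
                      locations = "HT7", baseline_effects = list(palm),
                      noise_sd = 0, gain_sigma = 0)
  gs <- generate_study(tpl, des, seed = 4)
  b <- get_map(gs$dataset, "S01", "baseline")
  s <- get_map(gs$dataset, "S01", "acupuncture:HT7")
  expect_gt(b$values[palmL[1], palmL[2]], 0.9)
  d <- subtract_baseline(suppressWarnings(normalize_unit_range(s)),
                         suppressWarnings(normalize_unit_range(b)))
  expect_equal(max(abs(d$values)), 0)
})

test_that("effect prevalence is realized at the stated rate", {
  tpl <- make_synthetic_template(32, 32, "rectangle")
  blob <- effect_spec("blob", center = c(16, 8), scale = 2, amplitude = 1,
                      prevalence = 0.3)
  hits <- vapply(1:200, function(i) {
    m <- generate_subject_map(tpl, list(blob), noise_sd = 0, seed = 1000 + i)
    max(m$values) > 0.5
  }, logical(1))
  p <- mean(hits)
  expect_lt(abs(p - 0.3), 3 * sqrt(0.3 * 0.7 / 200))
})

test_that("null studies carry no signal: nominal pixel rate on differences", {
  tpl <- make_synthetic_template(48, 48, "rectangle", n_views = 1)
  ds <- generate_null_study(tpl, n_subjects = 20, noise_sd = 1, seed = 6)
  stk <- condition_stack(ds, "acupuncture", "HT7", baseline_correct = TRUE)
  st <- one_sample_tmap(stk, tpl)
  frac <- mean(st$p[tpl$mask & st$valid] < 0.05)
  npx <- sum(tpl$mask)
  expect_lt(abs(frac - 0.05), 5 * sqrt(0.05 * 0.95 / npx))

  ds2 <- generate_null_study(tpl, n_subjects = 20, noise_sd = 1, seed = 7)
  expect_false(identical(ds$maps[[1]]$values, ds2$maps[[1]]$values))
})

test_that("condition_stack names the subject when a baseline is missing", {
  tpl <- make_synthetic_template(16, 16, "rectangle")
  ds <- generate_null_study(tpl, n_subjects = 3, seed = 1)
  ds$maps[["S02|baseline"]] <- NULL
  expect_error(condition_stack(ds, "acupuncture", "HT7", baseline_correct = TRUE),
               "S02 has no baseline")
})
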