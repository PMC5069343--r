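test_that("two-way ANOVA matches the sums-of-squares oracle on balanced data", {
  set.seed(201)
  for (rep in 1:10) {
    sc <- random_balanced_item(n_per_cell = 25)
    got <- two_way_anova(sc)
    ora <- anova_ss_oracle(sc)
    for (eff in c("stimulus", "location", "interaction")) {
      expect_equal(got[[paste0("F_", eff)]], ora[[paste0("F_", eff)]],
                   tolerance = 1e-8)
      expect_equal(got[[paste0("p_", eff)]], ora[[paste0("p_", eff)]],
                   tolerance = 1e-8)
    }
    # grand decomposition: SS_total = SS_stim + SS_loc + SS_inter + SS_within
    expect_equal(sum(ora$ss[1:4]), ora$ss[["total"]], tolerance = 1e-8)
  }
})

test_that("ANOVA F is invariant to shift and positive rescaling", {
  set.seed(202)
  sc <- random_balanced_item(n_per_cell = 10)
  f0 <- two_way_anova(sc)
  sc2 <- sc; sc2$score <- 3 * sc$score + 7
  f1 <- two_way_anova(sc2)
  expect_equal(f1$F_stimulus, f0$F_stimulus, tolerance = 1e-10)
  expect_equal(f1$F_interaction, f0$F_interaction, tolerance = 1e-10)
})

test_that("additive cell means with zero noise give zero interaction F", {
  g <- expand.grid(stimulus_type = c("acupuncture", "tactile"),
                   stimulus_location = c("HT7", "PC6"),
                   rep = 1:4, stringsAsFactors = FALSE)
  # means = row effect + column effect, plus a within-cell +/- wiggle that
  # cancels within every cell, so the residual MS is positive
  base <- ifelse(g$stimulus_type == "acupuncture", 2, 1) +
    ifelse(g$stimulus_location == "HT7", 0.5, 0)
  g$score <- base + ifelse(g$rep <= 2, 0.1, -0.1)
  out <- two_way_anova(g)
  expect_equal(out$F_interaction, 0, tolerance = 1e-12)
  expect_gt(out$F_stimulus, 0)
})

test_that("identical scores everywhere are reported as degenerate", {
  g <- expand.grid(stimulus_type = c("acupuncture", "tactile"),
                   stimulus_location = c("HT7", "PC6"),
                   rep = 1:3, stringsAsFactors = FALSE)
  g$score <- 2
  out <- two_way_anova(g)
  expect_true(out$degenerate)
  expect_true(is.na(out$F_stimulus))
  expect_equal(attr(out, "cell_means")["acupuncture", "HT7"], 2)
})

test_that("ANOVA rejects broken designs", {
  g <- random_balanced_item(3)
  expect_error(two_way_anova(g[g$stimulus_type == "acupuncture", ]),
               "two levels")
  g2 <- g[!(g$stimulus_type == "tactile" & g$stimulus_location == "HT7"), ]
  expect_error(two_way_anova(g2), "empty design cells")
})

test_that("Bonferroni flags nest inside uncorrected flags", {
  fl <- bonferroni_flags(c(0.0001, 0.03, 1.0), m = 13, alpha = 0.05)
  expect_equal(fl$corrected, c(TRUE, FALSE, FALSE))    # 0.0001 < 0.05/13
  expect_equal(fl$uncorrected, c(TRUE, TRUE, FALSE))   # 0.03 uncorrected-only
  set.seed(203)
  p <- runif(13)
  fl2 <- bonferroni_flags(p)
  expect_true(all(!fl2$corrected | fl2$uncorrected))   # corrected => uncorrected
  expect_error(bonferroni_flags(runif(20), m = 13), "family size")
})

test_that("intensity matrix orders conditions and computes means/SEMs", {
  one <- expand.grid(subject_id = "S01",
                     stimulus_type = c("acupuncture", "tactile"),
                     stimulus_location = c("HT7", "PC6", "ST36", "SP10"),
                     item = 1:13, stringsAsFactors = FALSE)
  one$score <- 2
  im <- intensity_matrix(one)
  expect_equal(dim(im), c(13, 8))
  expect_equal(colnames(im)[c(1, 5)], c("acupuncture:HT7", "tactile:HT7"))
  expect_true(all(im == 2))
  expect_true(all(attr(im, "sems") == 0))

  two <- rbind(one, transform(one, subject_id = "S02", score = 0))
  im2 <- intensity_matrix(two)
  expect_true(all(im2 == 1))                           # mean of {0, 2}
  expect_true(all(abs(attr(im2, "sems") - 1) < 1e-12)) # SEM of {0, 2} is 1

  bad <- one; bad$score[1] <- 5
  expect_error(intensity_matrix(bad), "0..3")
})

test_that("simulated questionnaires recover their target cell means", {
  # target row shaped like a strong stimulus effect (acupuncture > tactile)
  target <- matrix(0.5, 13, 8,
                   dimnames = list(paste0("Q", 1:13),
                                   c(paste("acupuncture", c("HT7","PC6","ST36","SP10"), sep = ":"),
                                     paste("tactile", c("HT7","PC6","ST36","SP10"), sep = ":"))))
  target[2, ] <- c(1.2, 1.3, 0.8, 0.8, 0.4, 0.6, 0.6, 0.6)
  tpl <- make_synthetic_template(16, 16, "rectangle")
  des <- study_design(n_subjects = 25, noise_sd = 0.05,
                      questionnaire_means = target)
  gs <- generate_study(tpl, des, seed = 301)
  im <- intensity_matrix(gs$dataset$questionnaire)
  sems <- attr(im, "sems")
  expect_true(all(abs(im[2, ] - target[2, ]) <= 3 * pmax(sems[2, ], 0.05)))
  # and the full ANOVA pipeline flags the planted stimulus effect on Q2
  an <- deqi_anova(gs$dataset$questionnaire)
  expect_true(an$sig_stimulus_bonferroni[an$item == "Q2"])
})
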