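STIMULUS_TYPES <- c("acupuncture", "tactile")
LOCATIONS <- c("HT7", "PC6", "ST36", "SP10")
N_ITEMS <- 13L

#' Two-way ANOVA for one questionnaire item
#'
#' Classical fixed-effects two-way analysis of variance with interaction
#' on the per-session scores of a single item: stimulus type (2 levels) x
#' stimulus location (4 levels). Fitted with [stats::aov()]; on a
#' balanced design the sequential decomposition equals the textbook
#' sums-of-squares split. Cell means and standard errors of the mean are
#' returned alongside. With `repeated = TRUE`, subject enters as an
#' additive blocking factor (the design is within-subject; the
#' fixed-effects analysis that ignores this is the default).
#'
#' @param scores data.frame with columns `stimulus_type`,
#'   `stimulus_location`, `score` (and `subject_id` when `repeated`).
#' @param repeated add `subject_id` as a blocking factor.
#' @return one-row data.frame: F, p and df pairs for the stimulus,
#'   location and interaction effects, plus a `degenerate` flag (TRUE when
#'   the within-cell variance is zero so F is undefined) and attributes
#'   `cell_means` / `cell_sems` (stimulus x location matrices).
#' @export
two_way_anova <- function(scores, repeated = FALSE) {
  need <- c("stimulus_type", "stimulus_location", "score")
  if (!all(need %in% names(scores)))
    stop("scores must have columns: ", paste(need, collapse = ", "))
  stim <- factor(scores$stimulus_type)
  u <- unique(scores$stimulus_location)
  loc <- factor(scores$stimulus_location,
                levels = c(intersect(LOCATIONS, u), sort(setdiff(u, LOCATIONS))))
  if (nlevels(stim) < 2 || nlevels(loc) < 2)
    stop("both factors need at least two levels")
  counts <- table(stim, loc)
  if (any(counts == 0)) stop("empty design cells")
  if (any(counts < 2)) stop("at least 2 observations per cell are required")
  df <- data.frame(score = scores$score, stim = stim, loc = loc)
  if (repeated) {
    if (!"subject_id" %in% names(scores))
      stop("repeated = TRUE requires a subject_id column")
    df$subject <- factor(scores$subject_id)
    fit <- aov(score ~ subject + stim * loc, data = df)
  } else {
    fit <- aov(score ~ stim * loc, data = df)
  }
  sm <- summary(fit)[[1]]
  rn <- trimws(rownames(sm))
  pick <- function(term) {
    i <- match(term, rn)
    c(F = sm[i, "F value"], p = sm[i, "Pr(>F)"], df1 = sm[i, "Df"],
      df2 = sm[match("Residuals", rn), "Df"])
  }
  s <- pick("stim"); l <- pick("loc"); il <- pick("stim:loc")
  ss_within <- sm[match("Residuals", rn), "Sum Sq"]
  # F is undefined when the within-cell variance vanishes (relative to the
  # response scale, guarding against rounding in aov's decomposition)
  degenerate <- ss_within <= 1e-20 * max(sum(df$score^2), .Machine$double.xmin)
  if (degenerate) s[c("F", "p")] <- l[c("F", "p")] <- il[c("F", "p")] <- NA_real_
  out <- data.frame(F_stimulus = s["F"], p_stimulus = s["p"],
                    df1_stimulus = s["df1"], df2_stimulus = s["df2"],
                    F_location = l["F"], p_location = l["p"],
                    df1_location = l["df1"], df2_location = l["df2"],
                    F_interaction = il["F"], p_interaction = il["p"],
                    df1_interaction = il["df1"], df2_interaction = il["df2"],
                    degenerate = degenerate, row.names = NULL)
  agg_m <- tapply(df$score, list(df$stim, df$loc), mean)
  agg_s <- tapply(df$score, list(df$stim, df$loc),
                  function(x) sd(x) / sqrt(length(x)))
  attr(out, "cell_means") <- agg_m
  attr(out, "cell_sems") <- agg_s
  out
}

#' Bonferroni significance flags
#'
#' Flags `p < alpha / m` (family-corrected) and `p < alpha`
#' (uncorrected). Corrected significance implies uncorrected
#' significance.
#'
#' @param p_values numeric vector of p-values.
#' @param m family size (defaults to the 13-item questionnaire).
#' @param alpha nominal level.
#' @return list with logical vectors `corrected` and `uncorrected`.
#' @export
bonferroni_flags <- function(p_values, m = N_ITEMS, alpha = 0.05) {
  if (m < length(p_values)) stop("family size m must cover the p-value list")
  list(corrected = p_values < alpha / m, uncorrected = p_values < alpha)
}

#' Item-wise factorial ANOVA over the whole questionnaire
#'
#' Runs [two_way_anova()] for each of the 13 items and attaches
#' Bonferroni flags (family size 13) per effect.
#'
#' @param questionnaire long-format data.frame (see [study_dataset()]).
#' @param alpha nominal level for the flags.
#' @inheritParams two_way_anova
#' @return data.frame with one row per item.
#' @export
deqi_anova <- function(questionnaire, alpha = 0.05, repeated = FALSE) {
  questionnaire <- .check_questionnaire(questionnaire)
  items <- sort(unique(questionnaire$item))
  rows <- lapply(items, function(it) {
    sub <- questionnaire[questionnaire$item == it, ]
    cbind(data.frame(item = paste0("Q", it)), two_way_anova(sub, repeated))
  })
  out <- do.call(rbind, rows)
  for (eff in c("stimulus", "location", "interaction")) {
    fl <- bonferroni_flags(out[[paste0("p_", eff)]], m = N_ITEMS, alpha = alpha)
    out[[paste0("sig_", eff, "_bonferroni")]] <- fl$corrected
    out[[paste0("sig_", eff, "_uncorrected")]] <- fl$uncorrected
  }
  out
}

#' Item-by-condition intensity matrix
#'
#' Mean score (and SEM) of every item under each of the 8 conditions,
#' ordered acupuncture HT7, PC6, ST36, SP10 then tactile HT7, PC6, ST36,
#' SP10 — the color-coded matrix view of questionnaire intensities.
#'
#' @param questionnaire long-format data.frame with scores in 0..3.
#' @return 13 x 8 matrix of means (rows Q1..Q13) with a matching
#'   `"sems"` matrix attribute.
#' @export
intensity_matrix <- function(questionnaire) {
  questionnaire <- .check_questionnaire(questionnaire)
  conds <- expand.grid(location = LOCATIONS, stimulus_type = STIMULUS_TYPES,
                       stringsAsFactors = FALSE)[, c(2, 1)]
  cn <- paste(conds$stimulus_type, conds$location, sep = ":")
  items <- paste0("Q", seq_len(N_ITEMS))
  means <- sems <- matrix(NA_real_, N_ITEMS, nrow(conds),
                          dimnames = list(items, cn))
  for (i in seq_len(N_ITEMS)) for (j in seq_len(nrow(conds))) {
    x <- questionnaire$score[questionnaire$item == i &
                             questionnaire$stimulus_type == conds$stimulus_type[j] &
                             questionnaire$stimulus_location == conds$location[j]]
    if (length(x)) {
      means[i, j] <- mean(x)
      sems[i, j] <- if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
    }
  }
  attr(means, "sems") <- sems
  means
}
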