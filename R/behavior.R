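#' Within-subject z-scoring of response times
#'
#' Centers and scales each subject's correct-press RTs by that subject's
#' own mean and sample SD (n - 1 denominator).
#'
#' @param rt numeric response times, s.
#' @param subject subject identifier, same length as `rt`.
#' @return numeric vector of z-scores (NA where `rt` is NA).
#' @export
zscore_within <- function(rt, subject) {
  stopifnot(length(rt) == length(subject))
  out <- rep(NA_real_, length(rt))
  for (s in unique(subject)) {
    i <- which(subject == s & !is.na(rt))
    if (length(i) < 2) stop("need at least 2 RTs per subject: ", s)
    sdv <- stats::sd(rt[i])
    if (sdv == 0) stop("zero RT variance for subject ", s)
    out[i] <- (rt[i] - mean(rt[i])) / sdv
  }
  out
}

#' Flag RT outliers outside the subject's 2-SD band
#'
#' A trial is flagged iff its RT lies strictly outside
#' `[mean - k SD, mean + k SD]` of that subject's RTs (an RT exactly on
#' the bound is kept).
#'
#' @inheritParams zscore_within
#' @param k SD multiplier (default 2).
#' @return logical vector (NA where `rt` is NA).
#' @export
flag_rt_outliers <- function(rt, subject, k = 2) {
  stopifnot(length(rt) == length(subject))
  out <- rep(NA, length(rt))
  for (s in unique(subject)) {
    i <- which(subject == s & !is.na(rt))
    m <- mean(rt[i]); sdv <- stats::sd(rt[i])
    out[i] <- abs(rt[i] - m) > k * sdv
  }
  out
}

#' Chi-square goodness-of-fit test on group counts
#'
#' Pearson statistic against expected proportions (uniform by default),
#' df = k - 1, upper-tail p.
#'
#' @param counts non-negative group counts.
#' @param p expected proportions (default uniform); must sum to 1.
#' @return list: statistic, df, p.value, expected.
#' @export
chi_square_gof <- function(counts, p = NULL) {
  stopifnot(all(counts >= 0), length(counts) >= 2)
  if (is.null(p)) p <- rep(1 / length(counts), length(counts))
  if (abs(sum(p) - 1) > 1e-8) stop("expected proportions must sum to 1")
  expected <- sum(counts) * p
  if (any(expected == 0)) stop("zero expected count")
  ct <- suppressWarnings(stats::chisq.test(counts, p = p))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value), expected = expected)
}

#' One-way ANOVA across drug groups
#'
#' Standard between/within decomposition. Two F reports are returned:
#' the conventional omnibus test on k - 1 numerator df, and a single-df
#' variant from a linear (numeric-coded) group contrast, matching the
#' alternative df convention that appears in some group-comparison
#' tables. Neither is privileged; both are reported.
#'
#' @param values numeric outcome.
#' @param group grouping factor (3 drug arms in the study design).
#' @return list: `omnibus` (F, df1, df2, p) and `single_df` (F, df1,
#'   df2, p).
#' @export
oneway_anova <- function(values, group) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2, all(table(group) >= 2))
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  if (tab["Residuals", "Sum Sq"] == 0 && tab[1, "Sum Sq"] > 0)
    stop("zero within-group variance with unequal means")
  omnibus <- list(F = tab[1, "F value"], df1 = tab[1, "Df"],
                  df2 = tab["Residuals", "Df"], p = tab[1, "Pr(>F)"])
  lin <- stats::lm(values ~ as.numeric(group))
  at <- stats::anova(lin)
  single <- list(F = at[1, "F value"], df1 = at[1, "Df"],
                 df2 = at["Residuals", "Df"], p = at[1, "Pr(>F)"])
  list(omnibus = omnibus, single_df = single)
}

#' Pooled mean over groups
#'
#' Sample-size-weighted mean of per-group means.
#'
#' @param n group sizes.
#' @param m group means.
#' @param digits rounding for the printed value (1 dp, table style).
#' @return pooled mean, rounded to `digits`.
#' @export
pooled_mean <- function(n, m, digits = 1) {
  stopifnot(length(n) == length(m), all(!is.na(n)), all(n > 0))
  round(sum(n * m) / sum(n), digits)
}

#' Pooled percentage over groups
#'
#' Reconstructs integer counts from per-group percentages
#' (`round(p_g / 100 * n_g)`), pools them, and returns the overall
#' percentage to 1 dp.
#'
#' @param n group sizes.
#' @param pct group percentages (0-100).
#' @param digits rounding of the result.
#' @return pooled percentage.
#' @export
pooled_percent <- function(n, pct, digits = 1) {
  stopifnot(length(n) == length(pct), all(!is.na(n)), all(n > 0))
  counts <- round(pct / 100 * n)
  round(100 * sum(counts) / sum(n), digits)
}

#' Prepare response times for modelling
#'
#' Keeps correct-press trials, z-scores RT within subject, and flags
#' 2-SD outliers on the raw RTs (equivalent to flagging on the z-scores,
#' since the transform is a per-subject affine map).
#'
#' @param rts output of [simulate_rts()] (or a table with the same
#'   columns).
#' @return data.frame of correct trials with rt_z and outlier columns;
#'   attribute `excluded_fraction` records the flagged share.
#' @export
prepare_rt <- function(rts) {
  d <- rts[rts$press_status == "correct" & !is.na(rts$rt), , drop = FALSE]
  d$rt_z <- zscore_within(d$rt, d$subject_id)
  d$outlier <- flag_rt_outliers(d$rt, d$subject_id)
  attr(d, "excluded_fraction") <- mean(d$outlier)
  d
}

#' Group-comparison battery for a subject table
#'
#' Chi-square goodness-of-fit tests of group sizes and sex counts
#' against uniform expectation, one-way ANOVAs of age, BMI, and hours
#' from pill, a 3 x 2 independence test of condition-guess correctness,
#' and pooled summaries.
#'
#' @param subjects output of [simulate_subject_table()].
#' @return list of test results mirroring the demographic table rows.
#' @export
behavior_battery <- function(subjects) {
  n_g <- table(factor(subjects$drug, levels = DRUG_LEVELS))
  n_f <- table(factor(subjects$drug[subjects$sex == "F"], levels = DRUG_LEVELS))
  guess_tab <- table(factor(subjects$drug, levels = DRUG_LEVELS),
                     subjects$correct_guess)
  list(
    n = as.vector(n_g),
    chi_n = chi_square_gof(as.vector(n_g)),
    chi_female = chi_square_gof(as.vector(n_f)),
    anova_age = oneway_anova(subjects$age, subjects$drug),
    anova_bmi = oneway_anova(subjects$bmi, subjects$drug),
    anova_hours = oneway_anova(subjects$hours_from_pill, subjects$drug),
    guess_independence = suppressWarnings(stats::chisq.test(guess_tab)),
    pooled_age = pooled_mean(as.vector(n_g),
                             tapply(subjects$age, subjects$drug, mean)[DRUG_LEVELS]),
    pooled_correct_guess = pooled_percent(
      as.vector(n_g),
      100 * tapply(subjects$correct_guess, subjects$drug, mean)[DRUG_LEVELS]))
}
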