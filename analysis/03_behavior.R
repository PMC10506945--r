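#!/usr/bin/env Rscript
# Stage 3: behavioural group checks and response-time preparation.
#
# Chi-square goodness-of-fit tests on group counts, one-way ANOVAs on
# demographics, pooled summaries, within-subject RT z-scores, 2-SD RT
# outlier flags, and the emotion x drug mixed model on z-scored RTs.

library(mimicrEMG)

seed <- 1L
config <- desk_config(seed = seed)
subjects <- simulate_subject_table(config, seed = seed + 2L)
rts <- simulate_rts(config, seed = seed + 1L)

bat <- behavior_battery(subjects)
message(sprintf("group sizes %s: chi-sq(%d) = %.2f, p = %.2f",
                paste(bat$n, collapse = "/"), bat$chi_n$df,
                bat$chi_n$statistic, bat$chi_n$p.value))
message(sprintf("age ANOVA: F(%d, %d) = %.2f, p = %.2f",
                bat$anova_age$omnibus$df1, bat$anova_age$omnibus$df2,
                bat$anova_age$omnibus$F, bat$anova_age$omnibus$p))
message(sprintf("pooled age %.1f; pooled correct-guess %.1f%%",
                bat$pooled_age, bat$pooled_correct_guess))

rt_prep <- prepare_rt(rts)
message(sprintf("RT outliers flagged: %.2f%% of correct trials",
                100 * attr(rt_prep, "excluded_fraction")))

fit <- rt_lmm(rt_prep)
message("RT LMM (", deparse(fit$formula), "):")
print(round(fit$anova[, c("NumDF", "DenDF", "F value", "Pr(>F)")], 3))

dir.create("results", showWarnings = FALSE)
write.csv(cbind(term = rownames(fit$anova), fit$anova),
          "results/rt_anova.csv", row.names = FALSE)
jsonlite::write_json(
  list(n = bat$n,
       chi_n = bat$chi_n[c("statistic", "df", "p.value")],
       chi_female = bat$chi_female[c("statistic", "df", "p.value")],
       pooled_age = bat$pooled_age,
       pooled_correct_guess = bat$pooled_correct_guess,
       rt_excluded_fraction = attr(rt_prep, "excluded_fraction")),
  "results/behaviour.json", auto_unbox = TRUE, digits = NA)
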