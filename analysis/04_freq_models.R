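#!/usr/bin/env Rscript
# Stage 4: frequentist linear mixed models on binned log EMG.
#
# One model per muscle (emotion x drug x time with by-subject slopes and
# stimulus intercepts, Satterthwaite F tests), followed by per-emotion
# simple slopes of the time course. Expectation under the null
# generator: strong emotion x time interactions (facial mimicry), no
# drug effects.

library(mimicrEMG)

seed <- 1L
config <- desk_config(seed = seed)
truth <- ground_truth()
prep <- preprocess_emg(simulate_emg(config, truth, seed = seed))

dir.create("results", showWarnings = FALSE)
for (m in c("ZM", "CS")) {
  fit <- fit_emg_lmm(prep$binned, m)
  message("\n== ", m, " (random-structure ladder step ",
          fit$reduction_step, ") ==")
  print(round(fit$anova[, c("NumDF", "DenDF", "F value", "Pr(>F)")], 4))
  sl <- simple_slopes(prep$binned, m)
  message("simple slopes (log units per 1-s window):")
  print(transform(sl, b = round(b, 4), SE = round(SE, 5),
                  z = round(z, 2), p = signif(p, 3)))
  write.csv(cbind(term = rownames(fit$anova), fit$anova),
            sprintf("results/anova_%s.csv", tolower(m)), row.names = FALSE)
  write.csv(sl, sprintf("results/slopes_%s.csv", tolower(m)),
            row.names = FALSE)
}
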