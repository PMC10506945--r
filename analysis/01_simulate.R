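#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study at desk scale.
#
# Emulates the placebo-controlled facial-mimicry experiment: three drug
# arms, dynamic happy/angry morph videos, two-channel facial EMG (ZM,
# CS), response times, and a demographic table. Drug effects are zero by
# default — the study's null — so every downstream stage should find
# clear mimicry but no drug modulation.

library(mimicrEMG)

seed <- 1L
out <- "results/data"
sig_out <- "scratch/simulated_signals"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- desk_config(seed = seed)
truth <- ground_truth()

message("design: ", 3 * config$n_subjects_per_group, " subjects, ",
        config$n_trials, " trials each, fs = ", config$fs, " Hz")

sim <- simulate_emg(config, truth, seed = seed)
# signal arrays are large and binary; they live under scratch/, the
# text tables under results/
write_simulation(sim, sig_out)
write.csv(sim$trials, file.path(out, "trials.csv"), row.names = FALSE)
message("raw EMG: ", nrow(sim$trials), " trials x 2 muscles, ",
        ncol(sim$signals$ZM), " samples each; ",
        sum(sim$trials$outlier), " amplitude-outlier trials injected")

rts <- simulate_rts(config, seed = seed + 1L)
write.csv(rts, file.path(out, "response_times.csv"), row.names = FALSE)
message("response times: ", sum(rts$press_status == "correct"),
        " correct presses of ", nrow(rts))

subjects <- simulate_subject_table(config, seed = seed + 2L)
write.csv(subjects, file.path(out, "subjects.csv"), row.names = FALSE)
message("subject table written; groups: ",
        paste(table(subjects$drug), collapse = "/"))
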