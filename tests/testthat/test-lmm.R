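# least-squares slope of the generating window trajectory, the target
# that a linear time term estimates on asymptotic data
lin_slope <- function(mu_w) unname(coef(lm(mu_w ~ I(1:5)))[2])

test_that("balanced noiseless linear data identifies the fixed effects", {
  # generative model linear in time, no random effects: the LMM must
  # reproduce it to numerical precision
  g <- expand.grid(subject = sprintf("S%02d", 1:6), window = 1:5,
                   emotion = EMOTION_LEVELS, stimulus = 1:4,
                   stringsAsFactors = FALSE)
  g$drug <- DRUG_LEVELS[(as.integer(factor(g$subject)) - 1) %% 3 + 1]
  e <- ifelse(g$emotion == "AngryToHappy", 1, -1)
  d_shift <- c(amisulpride = 0.03, naltrexone = -0.02, placebo = 0)[g$drug]
  g$muscle <- "ZM"
  set.seed(9)
  g$log_emg <- 0.05 * e + 0.02 * e * g$window - 0.01 * g$window +
    d_shift + rnorm(nrow(g), 0, 1e-7)
  fit <- fit_emg_lmm(g, "ZM", center_time = FALSE,
                     ladder = "(1 | subject) + (1 | stimulus)")
  expect_lt(max(abs(predict(fit$model) - g$log_emg)), 1e-5)
  # the fitted emotion x time interaction equals the generating 0.02
  # (sum contrasts: coefficient is half the level difference)
  co <- fit$coefficients
  expect_lt(abs(co["emotion1:time_c", "Estimate"] - (-0.02)), 1e-5)
  expect_lt(abs(co["time_c", "Estimate"] - (-0.01)), 1e-5)
})

test_that("F statistics are invariant to response rescaling", {
  b <- simulate_binned(tiny_config(n_subjects_per_group = 4),
                       ground_truth(), seed = 9)
  f1 <- fit_emg_lmm(b, "ZM", ladder = "(1 | subject) + (1 | stimulus)")
  b2 <- b; b2$log_emg <- 3.7 * b2$log_emg
  f2 <- fit_emg_lmm(b2, "ZM", ladder = "(1 | subject) + (1 | stimulus)")
  expect_equal(f1$anova[, "F value"], f2$anova[, "F value"],
               tolerance = 1e-6)
})

test_that("a generated emotion-by-time interaction is detected", {
  cfg <- tiny_config(n_subjects_per_group = 7, n_trials = 12,
                     n_videos = 12)
  tr <- ground_truth()   # opposite-sign ZM asymptotes by emotion
  hits <- 0
  for (i in 1:8) {
    b <- simulate_binned(cfg, tr, seed = 700 + i)
    fit <- fit_emg_lmm(b, "ZM",
                       ladder = c("(1 + emotion + time_c || subject) + (1 | stimulus)",
                                  "(1 | subject) + (1 | stimulus)"))
    hits <- hits + (fit$anova["emotion:time_c", "Pr(>F)"] < 0.001)
  }
  expect_gte(hits, 7)
})

test_that("null drug effects give calibrated omnibus drug tests", {
  cfg <- tiny_config(n_subjects_per_group = 6)
  tr <- ground_truth()
  p <- vapply(1:60, function(i) {
    b <- simulate_binned(cfg, tr, seed = 4000 + i)
    fit <- fit_emg_lmm(b, "ZM", ladder = "(1 | subject) + (1 | stimulus)")
    fit$anova["drug", "Pr(>F)"]
  }, numeric(1))
  expect_gt(mean(p > 0.05), 0.85)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("simple slopes recover and mirror the generating trends", {
  cfg <- tiny_config(n_subjects_per_group = 12, n_trials = 16,
                     n_videos = 8)
  tr <- ground_truth(a_cell = c(-0.12, 0.08, 0.12, -0.1),
                     sd_subject_a = 0.02, sd_subject_c = 0.05,
                     sd_subject_b = 0.01, sigma_resid = 0.15)
  target <- vapply(c("ZM.HappyToAngry", "ZM.AngryToHappy"), function(k)
    lin_slope(asymptotic_curve(tr$a_cell[k], 0, -0.5, 1:5)), numeric(1))
  got <- sapply(42:44, function(sd) {
    ss <- simple_slopes(simulate_binned(cfg, tr, seed = sd), "ZM")
    expect_true(all(ss$z == ss$b / ss$SE))
    ss$b[match(c("HappyToAngry", "AngryToHappy"), ss$emotion)]
  })
  med <- apply(got, 1, median)
  expect_lt(abs(med[1] - target[1]), 0.2 * abs(target[1]))
  expect_lt(abs(med[2] - target[2]), 0.2 * abs(target[2]))

  # symmetric +s / -s generator: recovered slopes nearly cancel
  tr_sym <- ground_truth(a_cell = c(-0.1, 0, 0.1, 0), sd_subject_a = 0.02,
                         sd_subject_b = 0.01, sd_subject_c = 0.05,
                         sigma_resid = 0.15)
  ss2 <- simple_slopes(simulate_binned(cfg, tr_sym, seed = 43), "ZM")
  expect_lt(abs(sum(ss2$b)), 0.015)
})

test_that("the reduction ladder is descended only on failure and recorded", {
  b <- simulate_binned(tiny_config(n_subjects_per_group = 4),
                       ground_truth(), seed = 51)
  fit <- fit_emg_lmm(b, "CS", ladder = "(1 | subject) + (1 | stimulus)")
  expect_equal(fit$reduction_step, 1)
  expect_true(fit$converged)
  expect_error(
    fit_lmm(log_emg ~ emotion, "(1 | nonexistent_column)",
            prep_lmm_data(b[b$muscle == "CS", ])),
    "no model on the reduction ladder")
})

test_that("null RT models rarely flag drug effects", {
  cfg <- tiny_config(n_subjects_per_group = 6)
  ns <- 0
  for (i in 1:15) {
    rp <- prepare_rt(simulate_rts(cfg, seed = 900 + i))
    fit <- rt_lmm(rp)
    ps <- fit$anova[, "Pr(>F)"]
    ns <- ns + all(ps[rownames(fit$anova) != "emotion"] > 0.05)
  }
  expect_gte(ns, 12)
})
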