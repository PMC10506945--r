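test_that("filter chain attenuates line noise and recovers sine envelopes", {
  fs <- 1200
  t <- seq(0, 4, by = 1 / fs)
  spec <- filter_spec()
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))

  # 50 Hz line interference is suppressed below 1% by the notch
  s50 <- 3 * sin(2 * pi * 50 * t)
  y <- filter_linear(s50, fs, spec)
  expect_lt(sqrt(mean(y[mid]^2)), 0.01 * sqrt(mean(s50^2)))

  # full-wave rectified 100 Hz sine smooths to its mean 2A/pi
  A <- 2.5
  env <- filter_chain(A * sin(2 * pi * 100 * t), fs, spec)
  expect_lt(abs(mean(env[mid]) / (2 * A / pi) - 1), 0.03)

  # DC sits outside the 20 Hz high-pass edge
  env_dc <- filter_chain(rep(5, length(t)), fs, spec)
  expect_lt(max(abs(env_dc[mid])), 1e-3)  # residual is filtfilt edge leakage
})

test_that("pre-rectification stages are linear", {
  fs <- 1200
  set.seed(41)
  x <- rnorm(3000); y <- rnorm(3000)
  fx <- filter_linear(x, fs)
  fy <- filter_linear(y, fs)
  fxy <- filter_linear(x + y, fs)
  expect_lt(max(abs(fxy - (fx + fy))) / max(abs(fxy)), 1e-8)
})

test_that("sampling rates below twice the band edge are refused", {
  expect_error(filter_chain(rnorm(1000), fs = 600, filter_spec()),
               "sampling rate")
  expect_silent(invisible(filter_chain(rnorm(1000), fs = 600,
                                       desk_filter_spec())))
})

test_that("epoching normalises to the 500 ms pre-onset baseline", {
  fs <- 200
  env <- rep(5, 6 * fs + 1)
  ep <- epoch_and_normalize(env, fs, onset_sample = fs + 1)
  expect_true(all(abs(ep$values - 1) < 1e-12))
  expect_equal(ep$baseline_mean, 5)

  env2 <- c(rep(4, fs), rep(8, 5 * fs + 1))
  ep2 <- epoch_and_normalize(env2, fs, onset_sample = fs + 1)
  expect_true(all(abs(ep2$values[ep2$time >= 0] - 2) < 1e-12))

  expect_error(epoch_and_normalize(rep(0, 6 * fs + 1), fs, fs + 1),
               "baseline")
  expect_error(epoch_and_normalize(rep(1, 100), fs, fs + 1), "cover")
})

test_that("binning takes half-open 1-s windows on the log scale", {
  fs <- 100
  time <- seq(-0.5, 5, by = 1 / fs)
  ones <- list(values = rep(1, length(time)), time = time)
  expect_equal(bin_log_windows(ones), rep(0, 5))

  v <- rep(1, length(time))
  v[time >= 2 & time < 3] <- exp(1)   # window 3 only
  expect_equal(bin_log_windows(list(values = v, time = time)),
               c(0, 0, 1, 0, 0))

  # floor guards the log against silent windows
  z <- list(values = rep(0, length(time)), time = time)
  expect_equal(bin_log_windows(z), rep(log(1e-4), 5))
})

test_that("outlier rules flag the planted trial and only it", {
  set.seed(7)
  st <- data.frame(subject = "S1", muscle = "ZM", trial_index = 1:21,
                   mean_val = c(rnorm(20, 1, 0.02), 10),
                   peak_val = rep(2, 21), base_mean = rep(1, 21),
                   base_peak = rep(1.5, 21))
  rep_ <- detect_outlier_trials(st)
  expect_identical(which(rep_$flags$mean_rule), 21L)
  expect_identical(which(rep_$flags$excluded), 21L)
  expect_equal(rep_$excluded_fraction, 1 / 21)

  # all trials identical: zero SD, nothing flagged
  same <- data.frame(subject = "S1", muscle = "CS", trial_index = 1:5,
                     mean_val = 1, peak_val = 2, base_mean = 1,
                     base_peak = 1.2)
  expect_equal(sum(detect_outlier_trials(same)$flags$excluded), 0)

  expect_error(detect_outlier_trials(same[1:2, ]), "at least 3")
})

test_that("outlier rules agree with a brute-force reimplementation", {
  set.seed(73)
  for (r in 1:40) {
    st <- random_outlier_stats(n_trials = sample(5:30, 1))
    for (rule in c("union", "intersection")) {
      mine <- detect_outlier_trials(st, rule = rule)$flags
      oracle <- brute_outliers(st, rule = rule)
      expect_identical(mine$excluded, oracle$excluded)
      expect_identical(mine$mean_rule, oracle$mean_rule)
      expect_identical(mine$peak_rule, oracle$peak_rule)
      expect_identical(mine$baseline_rule, oracle$baseline_rule)
    }
  }
})

test_that("injected amplitude outliers are caught by the 2-SD rules", {
  # at the design's trial count co-occurring outliers cannot mask each
  # other under the single-pass SD (they can at much smaller counts)
  hits <- 0; total <- 0
  for (s in 1:2) {
    sim <- simulate_emg(tiny_config(n_subjects_per_group = 2,
                                    n_trials = 96, n_videos = 24),
                        ground_truth(outlier_rate = 0.05), seed = 500 + s)
    prep <- preprocess_emg(sim)
    injected <- sim$trials[sim$trials$outlier, c("subject_id", "trial_index")]
    if (nrow(injected) == 0) next
    fl <- prep$outliers$flags
    for (i in seq_len(nrow(injected))) {
      total <- total + 1
      caught <- all(fl$excluded[fl$subject == injected$subject_id[i] &
                                fl$trial_index == injected$trial_index[i]])
      hits <- hits + caught
    }
  }
  expect_gt(total, 5)
  expect_gte(hits / total, 0.99)
})

test_that("pipeline closure: binned output recovers the generating windows", {
  cfg <- tiny_config(n_subjects_per_group = 4)
  tr <- ground_truth(sd_subject_a = 0, sd_subject_b = 0, sd_subject_c = 0,
                     sd_stimulus = 0, sigma_resid = 0, outlier_rate = 0)
  sim <- simulate_emg(cfg, tr, seed = 31)
  prep <- preprocess_emg(sim)
  mg <- merge(prep$binned, sim$truth_windows,
              by.x = c("subject", "trial_index", "muscle", "window"),
              by.y = c("subject_id", "trial_index", "muscle", "window"))
  expect_gt(nrow(mg), 100)
  # residual scatter reflects only the rectified-noise constant of the
  # smoothed envelope (~0.05 log units) plus baseline-estimation noise
  expect_lt(max(abs(mg$log_emg - mg$mu)), 0.3)
  expect_lt(mean(abs(mg$log_emg - mg$mu)), 0.05)
})

test_that("binned row count is 5 x kept trials x muscles per subject", {
  sp <- small_prep()
  fl <- sp$prep$outliers$flags
  binned <- sp$prep$binned
  for (s in unique(fl$subject)) {
    kept <- sum(!fl$excluded[fl$subject == s])
    expect_equal(sum(binned$subject == s), 5 * kept)
  }
})
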