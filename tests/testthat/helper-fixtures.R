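# Shared small fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, .fixtures)) assign(key, expr, .fixtures)
  get(key, .fixtures)
}

tiny_config <- function(...) {
  args <- list(n_subjects_per_group = 3, n_trials = 8, n_videos = 8,
               fs = 600)
  args[names(list(...))] <- list(...)
  do.call(design_config, args)
}

# one small simulated + preprocessed dataset reused across files
small_prep <- function() {
  with_cache("small_prep", {
    sim <- simulate_emg(tiny_config(n_subjects_per_group = 4),
                        ground_truth(outlier_rate = 0), seed = 11)
    list(sim = sim, prep = preprocess_emg(sim))
  })
}

# independent brute-force reimplementation of the 2-SD outlier rules,
# looping trial by trial (oracle for detect_outlier_trials)
brute_outliers <- function(stats, rule = "union", k = 2) {
  n <- nrow(stats)
  flag_cols <- c("mean_rule", "peak_rule", "baseline_rule", "excluded")
  res <- matrix(FALSE, n, 4, dimnames = list(NULL, flag_cols))
  for (i in seq_len(n)) {
    same <- which(stats$subject == stats$subject[i] &
                  stats$muscle == stats$muscle[i])
    dev <- function(col) {
      v <- stats[[col]][same]
      s <- sd(v)
      s > 0 && abs(stats[[col]][i] - mean(v)) > k * s
    }
    m <- dev("mean_val"); p <- dev("peak_val")
    b <- dev("base_mean") || dev("base_peak")
    res[i, ] <- c(m, p, b,
                  if (rule == "union") m || p || b else (m && p) || b)
  }
  as.data.frame(res)
}

# random per-trial summary tables for the outlier property tests
random_outlier_stats <- function(n_trials, n_subjects = 2) {
  do.call(rbind, lapply(seq_len(n_subjects), function(s)
    data.frame(subject = paste0("S", s),
               muscle = sample(c("ZM", "CS"), 1),
               trial_index = seq_len(n_trials),
               mean_val = rlnorm(n_trials, 0, 0.3),
               peak_val = rlnorm(n_trials, 0.5, 0.4),
               base_mean = rlnorm(n_trials, 0, 0.2),
               base_peak = rlnorm(n_trials, 0.3, 0.3))))
}

# naive double-loop WAIC (oracle for waic())
brute_waic <- function(ll) {
  S <- nrow(ll); N <- ncol(ll)
  elpd <- 0; p_eff <- 0
  for (i in seq_len(N)) {
    lppd_i <- log(mean(exp(ll[, i])))
    m <- mean(ll[, i])
    p_i <- sum((ll[, i] - m)^2) / (S - 1)
    elpd <- elpd + lppd_i - p_i
    p_eff <- p_eff + p_i
  }
  list(elpd = elpd, p_eff = p_eff, ic = -2 * elpd)
}

# term-by-term joint density of the asymptotic model (oracle for
# log_density), written as an explicit loop over observations
brute_log_density <- function(params, bd, spec = asymptotic_model_spec()) {
  drug_a <- "a" %in% spec$drug_on
  drug_c <- "c" %in% spec$drug_on
  ll <- 0
  for (i in seq_along(bd$y)) {
    s <- bd$sub[i]; k <- bd$sc[i]
    ia <- if (drug_a) bd$cell12[i] else k
    ic <- if (drug_c) bd$cell12[i] else k
    a_i <- params$a_fix[ia] + params$sd_a[k] * params$z_a[s, k]
    b_i <- params$sd_b[k] * params$z_b[s, k]
    c_i <- params$c_fix[ic] + params$sd_c[k] * params$z_c[s, k]
    mu <- a_i - (a_i - b_i) * exp(-exp(c_i) * (bd$t[i] - 1))
    ll <- ll + dnorm(bd$y[i], mu, params$sigma, log = TRUE)
  }
  lp <- 0
  for (v in params$a_fix)
    lp <- lp + dnorm(v, spec$prior_a[1], spec$prior_a[2], log = TRUE)
  for (v in params$c_fix)
    lp <- lp + dnorm(v, spec$prior_c[1], spec$prior_c[2], log = TRUE)
  for (z in c(params$z_a, params$z_b, params$z_c))
    lp <- lp + dnorm(z, 0, 1, log = TRUE)
  for (v in c(params$sd_a, params$sd_b, params$sd_c))
    lp <- lp + log(2) + dnorm(v, 0, spec$prior_re_sd, log = TRUE)
  lp <- lp + log(2) + dnorm(params$sigma, 0, spec$prior_sigma, log = TRUE)
  ll + lp
}

random_params <- function(J, n_a = 12, n_c = 12) {
  list(a_fix = rnorm(n_a, 0, 0.2), c_fix = rnorm(n_c, -1, 0.5),
       z_a = matrix(rnorm(J * 4), J, 4), z_b = matrix(rnorm(J * 4), J, 4),
       z_c = matrix(rnorm(J * 4), J, 4),
       sd_a = abs(rnorm(4, 0, 0.1)), sd_b = abs(rnorm(4, 0, 0.1)),
       sd_c = abs(rnorm(4, 0, 0.1)), sigma = runif(1, 0.1, 0.5))
}
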