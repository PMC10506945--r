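test_that("asymptotic curve honours its closed form", {
  # y(1) = b exactly, for arbitrary parameters
  set.seed(2)
  for (r in 1:20) {
    a <- rnorm(1); b <- rnorm(1); cc <- rnorm(1)
    expect_identical(asymptotic_curve(a, b, cc, 1), b)
  }
  # the asymptote is approached as t grows
  expect_equal(asymptotic_curve(0.1, 0, 0.25, 1e6), 0.1)
  # frozen arbitrary-precision evaluation of the closed form
  expect_equal(asymptotic_curve(0.1, 0, 0.25, 5), 0.09941194304925366,
               tolerance = 1e-12)
  # monotone toward the asymptote, geometric decay of the gap
  y <- asymptotic_curve(0.4, 0, -0.2, 1:5)
  expect_true(all(diff(y) > 0))
  ratio <- (0.4 - y[-1]) / (0.4 - y[-5])
  expect_equal(ratio, rep(exp(-exp(-0.2)), 4), tolerance = 1e-12)
  y2 <- asymptotic_curve(-0.4, 0.1, -0.2, 1:5)
  expect_true(all(diff(y2) < 0))
})

test_that("log density matches a term-by-term oracle and guards support", {
  b <- simulate_binned(tiny_config(n_subjects_per_group = 2), ground_truth(),
                       seed = 14)
  bd <- bayes_data(b[sample(nrow(b), 120), ])
  spec <- asymptotic_model_spec()
  set.seed(15)
  for (r in 1:10) {
    p <- random_params(bd$J)
    expect_equal(log_density(p, bd, spec), brute_log_density(p, bd, spec),
                 tolerance = 1e-10)
  }
  # nested designs change the fixed-effect dimension
  spec_nd <- asymptotic_model_spec(drug_on = character(0))
  p4 <- random_params(bd$J, n_a = 4, n_c = 4)
  expect_equal(log_density(p4, bd, spec_nd),
               brute_log_density(p4, bd, spec_nd), tolerance = 1e-10)
  expect_error(log_density(p4, bd, spec), "fixed-effect")
  # out-of-support SDs
  p_bad <- random_params(bd$J); p_bad$sigma <- -1
  expect_identical(log_density(p_bad, bd, spec), -Inf)

  # doubling the data doubles the likelihood term, priors unchanged
  bd2 <- bayes_data(rbind(b[1:60, ], b[1:60, ]))
  bd1 <- bayes_data(b[1:60, ])
  p <- random_params(bd1$J)
  ll1 <- log_density(p, bd1, spec)
  ll2 <- log_density(p, bd2, spec)
  prior_part <- local({   # oracle prior computed independently
    lp <- sum(dnorm(p$a_fix, 0, 0.2, log = TRUE)) +
      sum(dnorm(p$c_fix, -1, 1, log = TRUE)) +
      sum(dnorm(c(p$z_a, p$z_b, p$z_c), 0, 1, log = TRUE)) +
      sum(log(2) + dnorm(c(p$sd_a, p$sd_b, p$sd_c), 0, 0.1, log = TRUE)) +
      log(2) + dnorm(p$sigma, 0, 0.5, log = TRUE)
    lp
  })
  expect_equal(ll2 - prior_part, 2 * (ll1 - prior_part), tolerance = 1e-8)

  # a single standard-normal observation on the curve contributes
  # -log(sqrt(2*pi)) to the likelihood
  b1 <- b[1, ]; b1$log_emg <- 0; b1$window <- 1
  bds <- bayes_data(b1)
  p0 <- list(a_fix = rep(0, 12), c_fix = rep(0, 12),
             z_a = matrix(0, 1, 4), z_b = matrix(0, 1, 4),
             z_c = matrix(0, 1, 4), sd_a = rep(0.1, 4), sd_b = rep(0.1, 4),
             sd_c = rep(0.1, 4), sigma = 1)
  prior0 <- sum(dnorm(rep(0, 12), 0, 0.2, log = TRUE)) +
    sum(dnorm(rep(0, 12), -1, 1, log = TRUE)) + 12 * dnorm(0, log = TRUE) +
    sum(log(2) + dnorm(rep(0.1, 12), 0, 0.1, log = TRUE)) +
    log(2) + dnorm(1, 0, 0.5, log = TRUE)
  expect_equal(log_density(p0, bds) - prior0, -0.5 * log(2 * pi),
               tolerance = 1e-10)
})

test_that("log density peaks when observations sit on their curve", {
  b <- simulate_binned(tiny_config(n_subjects_per_group = 2),
                       ground_truth(), seed = 18)[1:50, ]
  bd <- bayes_data(b)
  set.seed(19)
  p <- random_params(bd$J)
  # place every observation exactly on its curve value, then perturb one
  mu <- vapply(seq_along(bd$y), function(i) {
    k <- bd$sc[i]; s <- bd$sub[i]
    a_i <- p$a_fix[bd$cell12[i]] + p$sd_a[k] * p$z_a[s, k]
    b_i <- p$sd_b[k] * p$z_b[s, k]
    c_i <- p$c_fix[bd$cell12[i]] + p$sd_c[k] * p$z_c[s, k]
    asymptotic_curve(a_i, b_i, c_i, bd$t[i])
  }, numeric(1))
  bd$y <- mu
  base <- log_density(p, bd)
  for (i in c(1, 25, 50)) for (d in c(-0.3, 0.3)) {
    bd2 <- bd; bd2$y[i] <- bd2$y[i] + d
    expect_lt(log_density(p, bd2), base)
  }
})

test_that("split R-hat separates mixed from disjoint chains", {
  # brute-force evaluation of the split formula on a hand-set case
  x <- cbind(c(1, 2, 3, 4), c(101, 102, 103, 104))
  halves <- cbind(c(1, 2), c(3, 4), c(101, 102), c(103, 104))
  W <- mean(apply(halves, 2, var))
  B <- 2 * var(colMeans(halves))
  oracle <- sqrt(((2 - 1) / 2 * W + B / 2) / W)
  expect_equal(split_rhat(x), oracle, tolerance = 1e-12)
  expect_gt(split_rhat(x), 1.2)

  set.seed(44)
  mixed <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(mixed), 1.02)
  expect_true(is.nan(split_rhat(matrix(1, 100, 4))))
  expect_error(split_rhat(matrix(1, 2, 2)), "at least 4")

  # exchangeable draws: permuting within chains leaves R-hat ~ unchanged
  perm <- apply(mixed, 2, sample)
  expect_lt(abs(split_rhat(perm) - split_rhat(mixed)), 0.02)
})

test_that("HPDI is the narrowest mass-covering interval", {
  set.seed(55)
  x <- rnorm(4e5)
  h <- hpdi(x, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)

  e <- rexp(2e4)
  he <- hpdi(e, 0.9)
  expect_lt(he[1], 0.01)  # hugs the mode at zero

  # brute-force window search oracle
  brute_hpdi <- function(s, mass) {
    xs <- sort(s); n <- length(xs); w <- ceiling(mass * n)
    best <- c(Inf, NA, NA)
    for (i in 1:(n - w)) if (xs[i + w] - xs[i] < best[1])
      best <- c(xs[i + w] - xs[i], xs[i], xs[i + w])
    best[2:3]
  }
  s <- rexp(500)
  expect_equal(hpdi(s, 0.8), brute_hpdi(s, 0.8))
  expect_error(hpdi(x, 1.2), "mass")
})

test_that("prior predictive curves reflect the declared priors", {
  pp <- prior_predictive(n_curves = 1e4, seed = 3)
  expect_true(all(pp$curves[, 1] == 0))           # b = 0 at t = 1
  expect_lt(abs(sd(pp$a) - 0.2), 0.01)            # Normal(0, 0.2)
  expect_lt(abs(mean(pp$c) + 1), 0.04)            # Normal(-1, 1)
  expect_identical(pp, prior_predictive(n_curves = 1e4, seed = 3))
})

test_that("prior-only sampling reproduces the prior moments", {
  spec <- asymptotic_model_spec(chains = 2, iter = 2000, adapt = 200)
  bd0 <- bayes_data(simulate_binned(tiny_config(n_subjects_per_group = 2),
                                    ground_truth(), seed = 1)[1:40, ])
  fit <- suppressWarnings(sample_posterior(bd0, spec, seed = 5,
                                           prior_only = TRUE))
  a1 <- as.vector(fit$draws[, , "a[amisulpride:ZM.HappyToAngry]"])
  c1 <- as.vector(fit$draws[, , "c[amisulpride:ZM.HappyToAngry]"])
  expect_lt(abs(mean(a1)), 0.02); expect_lt(abs(sd(a1) - 0.2), 0.02)
  expect_lt(abs(mean(c1) + 1), 0.1); expect_lt(abs(sd(c1) - 1), 0.1)
})

test_that("posterior sampling is seed-reproducible and labelled", {
  sp <- small_prep()
  bd <- bayes_data(sp$prep$binned[sp$prep$binned$subject %in%
                                    c("S001", "S005", "S009"), ])
  spec <- asymptotic_model_spec(chains = 2, iter = 400, adapt = 150)
  f1 <- suppressWarnings(sample_posterior(bd, spec, seed = 9))
  f2 <- suppressWarnings(sample_posterior(bd, spec, seed = 9))
  expect_identical(f1$draws, f2$draws)
  pn <- dimnames(f1$draws)[[3]]
  expect_equal(sum(grepl("^a\\[", pn)), 12)
  expect_equal(sum(grepl("^c\\[", pn)), 12)
  expect_equal(sum(grepl("^z_", pn)), 3 * 4 * bd$J)
  expect_true("sigma" %in% pn)
  expect_s3_class(f1$report, "convergence_report")
  sm <- posterior_summary(f1)
  expect_true(all(sm$hpdi_lower <= sm$mean & sm$mean <= sm$hpdi_upper))
})

test_that("the Gibbs backend agrees with an independent JAGS fit", {
  b <- simulate_binned(tiny_config(n_subjects_per_group = 3),
                       ground_truth(), seed = 23)
  bd <- bayes_data(b)
  spec <- asymptotic_model_spec(chains = 2, iter = 2400, adapt = 500)
  fg <- suppressWarnings(sample_posterior(bd, spec, seed = 6,
                                          backend = "gibbs"))
  fj <- suppressWarnings(sample_posterior(bd, spec, seed = 6,
                                          backend = "jags"))
  pn <- c(grep("^a\\[", dimnames(fg$draws)[[3]], value = TRUE),
          "sigma", paste0("sd_a[", cell4_labels(), "]"))
  for (p in pn) {
    g <- as.vector(fg$draws[, , p]); j <- as.vector(fj$draws[, , p])
    tol <- 0.2 * max(sd(g), sd(j)) + 0.002
    expect_lt(abs(mean(g) - mean(j)), tol)
    expect_lt(abs(sd(g) - sd(j)), 2 * tol)
  }
})

test_that("posterior draws are calibrated against prior-drawn truths", {
  # simulation-based calibration at small scale: the rank of the true
  # parameter among thinned posterior draws should be uniform
  cfg <- tiny_config(n_subjects_per_group = 1)
  base <- simulate_binned(cfg, ground_truth(), seed = 1)
  bd0 <- bayes_data(base)
  spec <- asymptotic_model_spec(chains = 2, iter = 900)
  pr <- gibbs_problem(bd0, spec)
  set.seed(77)
  L <- 16; nround <- 16
  ranks <- matrix(NA_real_, nround, 2)
  for (r in seq_len(nround)) {
    a <- rnorm(12, 0, 0.2); cc <- rnorm(12, -1, 1)
    sda <- abs(rnorm(4, 0, 0.1)); sdb <- abs(rnorm(4, 0, 0.1))
    sdc <- abs(rnorm(4, 0, 0.1)); sig <- abs(rnorm(1, 0, 0.5))
    za <- matrix(rnorm(bd0$J * 4), bd0$J)
    zb <- matrix(rnorm(bd0$J * 4), bd0$J)
    zc <- matrix(rnorm(bd0$J * 4), bd0$J)
    ai <- a[pr$ia] + sda[pr$sc] * za[cbind(pr$sub, pr$sc)]
    bi <- sdb[pr$sc] * zb[cbind(pr$sub, pr$sc)]
    ci <- cc[pr$ic] + sdc[pr$sc] * zc[cbind(pr$sub, pr$sc)]
    mu <- ai - (ai - bi) * exp(-exp(ci) * (pr$tt - 1))
    bdr <- bd0; bdr$y <- rnorm(pr$N, mu, sig)
    fit <- suppressWarnings(sample_posterior(bdr, spec, seed = 400 + r))
    idx <- round(seq(1, dim(fit$draws)[1], length.out = L / 2))
    d_a <- as.vector(fit$draws[idx, , dimnames(fit$draws)[[3]][1]])
    d_s <- as.vector(fit$draws[idx, , "sigma"])
    ranks[r, ] <- c(sum(d_a < a[1]), sum(d_s < sig))
  }
  # ranks range over 0..L; reject only clearly non-uniform patterns
  for (j in 1:2) {
    expect_gt(suppressWarnings(
      stats::ks.test(ranks[, j] / L, "punif"))$p.value, 0.005)
    expect_gt(mean(ranks[, j]), 0.2 * L)
    expect_lt(mean(ranks[, j]), 0.8 * L)
  }
})
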