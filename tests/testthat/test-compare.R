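test_that("the nested family drops drug terms and nothing else", {
  full <- asymptotic_model_spec()
  fam <- nested_family(full)
  expect_named(fam, c("full", "asymptote_only", "rate_only", "no_drug"))
  expect_equal(fam$full$drug_on, c("a", "c"))
  expect_equal(fam$asymptote_only$drug_on, "a")
  expect_equal(fam$rate_only$drug_on, "c")
  expect_length(fam$no_drug$drug_on, 0)
  # everything but the fixed design is structurally identical
  for (nm in names(fam)) {
    s <- fam[[nm]]; s$drug_on <- NULL; f <- full; f$drug_on <- NULL
    expect_identical(unclass(s), unclass(f))
  }
  expect_error(nested_family(fam$no_drug), "drug")

  # 12 + 12 fixed coefficients collapse to 4 + 4 without drug
  b <- simulate_binned(tiny_config(n_subjects_per_group = 2),
                       ground_truth(), seed = 2)[1:100, ]
  bd <- bayes_data(b)
  spec_small <- asymptotic_model_spec(chains = 1, iter = 40, adapt = 50,
                                      drug_on = character(0))
  fit <- suppressWarnings(sample_posterior(bd, spec_small, seed = 1))
  pn <- dimnames(fit$draws)[[3]]
  expect_equal(sum(grepl("^a\\[", pn)), 4)
  expect_equal(sum(grepl("^c\\[", pn)), 4)
})

test_that("WAIC reproduces the hand-computed example and the oracle", {
  ll <- matrix(c(-1, -1.2, -2, -2.2), nrow = 2)
  w <- waic(ll)
  expect_equal(w$p_eff, 0.04, tolerance = 1e-12)
  expect_equal(w$ic, 6.46003324471341, tolerance = 1e-9)

  # identical draws: no effective parameters
  ll0 <- matrix(rep(c(-1.3, -0.4, -2.2), each = 5), nrow = 5)
  w0 <- waic(ll0)
  expect_equal(w0$p_eff, 0)
  expect_equal(w0$ic, -2 * sum(ll0[1, ]))

  # translation: adding k to every entry shifts elpd by n*k
  set.seed(61)
  llr <- matrix(rnorm(200, -2), 20, 10)
  expect_equal(waic(llr + 0.7)$elpd, waic(llr)$elpd + 10 * 0.7,
               tolerance = 1e-10)

  # double-loop equivalence on random matrices
  for (r in 1:25) {
    S <- sample(2:100, 1); N <- sample(1:50, 1)
    m <- matrix(rnorm(S * N, -1.5, 0.8), S, N)
    expect_equal(waic(m)$elpd, brute_waic(m)$elpd, tolerance = 1e-10)
    expect_equal(waic(m)$p_eff, brute_waic(m)$p_eff, tolerance = 1e-10)
  }
  expect_error(waic(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("PSIS-LOO matches exact leave-one-out on a conjugate toy model", {
  # y_j ~ N(theta, 1), theta ~ N(0, 10): closed-form posterior and
  # closed-form leave-one-out predictive densities
  set.seed(71)
  n <- 20; y <- rnorm(n, 0.5, 1)
  post <- function(yy) {
    v <- 1 / (length(yy) / 1 + 1 / 100)
    list(m = v * sum(yy), v = v)
  }
  exact_loo <- sum(vapply(seq_len(n), function(i) {
    p <- post(y[-i])
    dnorm(y[i], p$m, sqrt(p$v + 1), log = TRUE)
  }, numeric(1)))
  p_full <- post(y)
  draws <- rnorm(4000, p_full$m, sqrt(p_full$v))
  ll <- vapply(seq_len(n), function(i) dnorm(y[i], draws, 1, log = TRUE),
               numeric(4000))
  res <- psis_loo(ll)
  expect_lt(abs(res$elpd - exact_loo), 2 * res$se)
  expect_true(all(res$pareto_k < 0.7, na.rm = TRUE))

  # smoothing off reduces to plain importance sampling; they agree when
  # the tails are benign
  res_plain <- psis_loo(ll, smooth = FALSE)
  expect_lt(abs(res$elpd - res_plain$elpd), 0.2)

  # identical draws: LOO elpd collapses to the total log likelihood
  ll0 <- matrix(rep(c(-1, -2), each = 4), 4)
  expect_equal(suppressWarnings(psis_loo(ll0))$elpd, -3)
})

test_that("LOO is not systematically more optimistic than WAIC", {
  # on well-behaved conjugate instances the two elpd estimates agree to
  # Monte-Carlo error, with LOO never optimistic beyond that error
  set.seed(81)
  for (r in 1:50) {
    n <- sample(10:25, 1)
    y <- rnorm(n, rnorm(1), 1)
    v <- 1 / (n + 1 / 100); m <- v * sum(y)
    draws <- rnorm(1000, m, sqrt(v))
    ll <- vapply(seq_len(n), function(i) dnorm(y[i], draws, 1, log = TRUE),
                 numeric(1000))
    expect_lte(suppressWarnings(psis_loo(ll))$elpd, waic(ll)$elpd + 0.05)
  }
})

test_that("generalised Pareto tail fitting recovers known shapes", {
  set.seed(91)
  for (k_true in c(0.1, 0.4, 0.7)) {
    x <- 1 / runif(3000)^k_true - 1   # GPD(k = k_true, sigma = k_true)
    fit <- gpd_fit(x)
    expect_lt(abs(fit$k - k_true), 0.1)
  }
})

test_that("information-criterion weights normalise and order models", {
  expect_equal(ic_weights(c(3, 3)), c(0.5, 0.5))
  w <- ic_weights(c(10, 12))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(ic_weights(c(110, 112)), w, tolerance = 1e-12)
  set.seed(3)
  crit <- rnorm(4, 100, 5)
  expect_equal(sum(ic_weights(crit)), 1, tolerance = 1e-9)
  expect_error(ic_weights(5), "at least 2")
})

test_that("the comparison table has the fixed row order and unit columns", {
  b <- simulate_binned(tiny_config(n_subjects_per_group = 2),
                       ground_truth(sd_subject_c = 0.1), seed = 6)
  bd <- bayes_data(b[b$window <= 5, ][1:300, ])
  spec <- asymptotic_model_spec(chains = 2, iter = 300, adapt = 150)
  fits <- fit_nested_family(bd, spec, seed = 4)
  cmp <- compare_models(fits)
  expect_equal(cmp$table$model,
               c("Full", "Drug effects asymptote only",
                 "Drug effects rate only", "No effect of drug"))
  expect_equal(sum(cmp$table$waic_weight), 1, tolerance = 1e-9)
  expect_equal(sum(cmp$table$loo_weight), 1, tolerance = 1e-9)
  expect_true(all(cmp$table$waic_weight >= 0 & cmp$table$waic_weight <= 1))
  # mismatched data refused
  fits_bad <- fits
  fits_bad$no_drug$bd <- bayes_data(b[1:200, ])
  expect_error(compare_models(fits_bad), "different observation counts")
})
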