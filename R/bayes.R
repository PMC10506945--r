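#' Asymptotic regression curve
#'
#' The three-parameter within-trial activation curve
#' \deqn{y(t) = a - (a - b)\,e^{-e^{c}\,(t - 1)}}
#' where `a` is the asymptote, `b` the starting value at `t = 1`
#' (so `y(1) = b` exactly), and `exp(c)` the strictly positive rate of
#' approach (log link on the rate). `t` is the 1-s window index, 1-5.
#'
#' @param a asymptote (log proportion-of-baseline units).
#' @param b starting value at t = 1.
#' @param c log rate.
#' @param t window index (>= 1); vectorised over all arguments.
#' @return curve value(s).
#' @export
asymptotic_curve <- function(a, b, c, t) {
  stopifnot(all(is.finite(a)), all(is.finite(b)), all(is.finite(c)),
            all(t >= 1))
  # algebraically a - (a - b) exp(-exp(c)(t - 1)); this arrangement makes
  # y(1) = b exact in floating point
  b + (a - b) * (1 - exp(-exp(c) * (t - 1)))
}

#' Specification of the hierarchical asymptotic Bayesian model
#'
#' Fixed-effect design: one coefficient of `a` and of `c` per
#' drug x muscle x emotion cell (12 cells, no global intercept); the
#' fixed effect of `b` is pinned to 0 (data are proportion of baseline).
#' Random effects: per-subject coefficients of a, b, and c for each of
#' the 4 muscle x emotion cells, non-centred, independent across cells,
#' each with its own SD. Priors: Normal(0, 0.2) on a-coefficients,
#' Normal(-1, 1) on c-coefficients, Half-Normal(0, 0.1) on every
#' random-effect SD, Half-Normal(0, 0.5) on the residual SD.
#'
#' `drug_on` controls which curve parameters keep the drug factor in
#' their fixed design; dropping it collapses 12 cells to the 4
#' muscle x emotion cells, which is how the nested model family is
#' built (see [nested_family()]).
#'
#' @param chains number of MCMC chains.
#' @param iter iterations per chain, warmup included.
#' @param warmup_frac fraction of `iter` discarded as warmup.
#' @param adapt sampler adaptation steps before warmup.
#' @param prior_a,prior_c (mean, sd) of the fixed-effect priors.
#' @param prior_re_sd Half-Normal scale of the random-effect SDs.
#' @param prior_sigma Half-Normal scale of the residual SD.
#' @param drug_on character subset of c("a", "c").
#' @return object of class `asymptotic_model_spec`.
#' @export
asymptotic_model_spec <- function(chains = 4, iter = 5000,
                                  warmup_frac = 0.5, adapt = 1000,
                                  prior_a = c(0, 0.2),
                                  prior_c = c(-1, 1),
                                  prior_re_sd = 0.1,
                                  prior_sigma = 0.5,
                                  drug_on = c("a", "c")) {
  stopifnot(chains >= 1, iter >= 4, warmup_frac > 0, warmup_frac < 1,
            prior_a[2] > 0, prior_c[2] > 0, prior_re_sd > 0,
            prior_sigma > 0, all(drug_on %in% c("a", "c")))
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup_frac = warmup_frac, adapt = as.integer(adapt),
                 prior_a = prior_a, prior_c = prior_c,
                 prior_re_sd = prior_re_sd, prior_sigma = prior_sigma,
                 drug_on = drug_on),
            class = "asymptotic_model_spec")
}

#' Index a binned log-EMG table for the Bayesian model
#'
#' Converts the long table to the integer index vectors the model uses:
#' observation response and window plus subject, muscle x emotion
#' subject-cell (1-4), and drug x muscle x emotion fixed cell (1-12).
#'
#' @param binned data.frame with columns subject, drug, emotion, muscle,
#'   window, log_emg.
#' @return list of class `bayes_data`: y, t, sub, sc, cell12, J (number
#'   of subjects), plus label vectors `subjects`, `cells4`, `cells12`.
#' @export
bayes_data <- function(binned) {
  need <- c("subject", "drug", "emotion", "muscle", "window", "log_emg")
  stopifnot(all(need %in% names(binned)), all(is.finite(binned$log_emg)))
  subjects <- sort(unique(as.character(binned$subject)))
  sc_lab <- cell4_labels()
  sc <- match(paste(binned$muscle, binned$emotion, sep = "."), sc_lab)
  d <- match(binned$drug, DRUG_LEVELS)
  if (anyNA(sc) || anyNA(d)) stop("observation references unknown cell levels")
  cells12 <- as.vector(outer(sc_lab, DRUG_LEVELS,
                             function(k, g) paste(g, k, sep = ":")))
  sub_idx <- match(as.character(binned$subject), subjects)
  sub_drug <- d[match(seq_along(subjects), sub_idx)]
  structure(list(y = binned$log_emg, t = binned$window,
                 sub = sub_idx,
                 sc = sc, cell12 = (d - 1L) * 4L + sc,
                 J = length(subjects), subjects = subjects,
                 sub_drug = sub_drug,
                 cells4 = sc_lab, cells12 = cells12),
            class = "bayes_data")
}

# fixed-design index and labels for parameter p ("a" or "c") under spec
fixed_design <- function(bd, spec, p) {
  if (p %in% spec$drug_on) list(idx = bd$cell12, labels = bd$cells12)
  else list(idx = bd$sc, labels = bd$cells4)
}

#' Joint log density of the hierarchical asymptotic model
#'
#' Sum of the Normal log likelihood of every observation around its
#' curve value (cell fixed effect plus subject random effects on a, b,
#' c) and all prior log densities (fixed effects, standard-normal
#' non-centred random effects, Half-Normal SD priors, Half-Normal
#' residual-SD prior). Returns `-Inf` for out-of-support values
#' (non-positive SDs).
#'
#' @param params list: a_fix, c_fix (fixed-effect vectors), z_a, z_b,
#'   z_c (J x 4 matrices of non-centred subject effects), sd_a, sd_b,
#'   sd_c (length-4 SDs), sigma (residual SD).
#' @param bd a [bayes_data()].
#' @param spec an [asymptotic_model_spec()].
#' @return scalar log density.
#' @export
log_density <- function(params, bd, spec = asymptotic_model_spec()) {
  ia <- fixed_design(bd, spec, "a"); ic <- fixed_design(bd, spec, "c")
  if (length(params$a_fix) != length(unique(ia$labels)) ||
      length(params$c_fix) != length(unique(ic$labels)))
    stop("fixed-effect vectors do not match the spec's design")
  if (max(bd$sub) > nrow(params$z_a)) stop("unknown subject index")
  with(params, {
    if (any(c(sd_a, sd_b, sd_c) < 0) || sigma <= 0) return(-Inf)
    ai <- a_fix[ia$idx] + (sd_a[bd$sc]) * z_a[cbind(bd$sub, bd$sc)]
    bi <- (sd_b[bd$sc]) * z_b[cbind(bd$sub, bd$sc)]
    ci <- c_fix[ic$idx] + (sd_c[bd$sc]) * z_c[cbind(bd$sub, bd$sc)]
    mu <- ai - (ai - bi) * exp(-exp(ci) * (bd$t - 1))
    ll <- sum(stats::dnorm(bd$y, mu, sigma, log = TRUE))
    lp <- sum(stats::dnorm(a_fix, spec$prior_a[1], spec$prior_a[2], log = TRUE)) +
      sum(stats::dnorm(c_fix, spec$prior_c[1], spec$prior_c[2], log = TRUE)) +
      sum(stats::dnorm(cbind(z_a, z_b, z_c), 0, 1, log = TRUE)) +
      sum(log(2) + stats::dnorm(c(sd_a, sd_b, sd_c), 0, spec$prior_re_sd,
                                log = TRUE)) +
      log(2) + stats::dnorm(sigma, 0, spec$prior_sigma, log = TRUE)
    ll + lp
  })
}

# JAGS source for the model implied by spec; prior_only drops the
# likelihood block
jags_model_string <- function(spec, prior_only = FALSE) {
  lik <- "
  for (i in 1:N) {
    ai[i] <- a_fix[ia[i]] + sd_a[sc[i]] * z_a[sub[i], sc[i]]
    bi[i] <- sd_b[sc[i]] * z_b[sub[i], sc[i]]
    ci[i] <- c_fix[ic[i]] + sd_c[sc[i]] * z_c[sub[i], sc[i]]
    mu[i] <- ai[i] - (ai[i] - bi[i]) * exp(-exp(ci[i]) * (t[i] - 1))
    y[i] ~ dnorm(mu[i], tau)
  }"
  paste0("model {", if (!prior_only) lik else "", "
  for (j in 1:J) { for (k in 1:4) {
    z_a[j, k] ~ dnorm(0, 1)
    z_b[j, k] ~ dnorm(0, 1)
    z_c[j, k] ~ dnorm(0, 1)
  } }
  for (m in 1:Ma) { a_fix[m] ~ dnorm(", spec$prior_a[1], ", ",
  1 / spec$prior_a[2]^2, ") }
  for (m in 1:Mc) { c_fix[m] ~ dnorm(", spec$prior_c[1], ", ",
  1 / spec$prior_c[2]^2, ") }
  for (k in 1:4) {
    sd_a[k] ~ dnorm(0, ", 1 / spec$prior_re_sd^2, ") T(0,)
    sd_b[k] ~ dnorm(0, ", 1 / spec$prior_re_sd^2, ") T(0,)
    sd_c[k] ~ dnorm(0, ", 1 / spec$prior_re_sd^2, ") T(0,)
  }
  sigma ~ dnorm(0, ", 1 / spec$prior_sigma^2, ") T(0,)
  tau <- 1 / (sigma * sigma)
}")
}

#' Sample the posterior of the hierarchical asymptotic model
#'
#' Default backend is the package's blocked Gibbs sampler (conjugate
#' updates for the conditionally linear asymptote/starting-value side,
#' adaptive Metropolis for the rate side, slice sampling for the
#' residual SD, and interweaved translation/scale moves along the
#' hierarchy's slow directions), targeting exactly the joint density of
#' [log_density()]. `backend = "jags"` instead delegates to JAGS
#' (adaptive conjugate/slice sampling) for the same model — useful as an
#' independent cross-check of the posterior. The first `warmup_frac` of
#' the `iter` iterations per chain is discarded as warmup. Convergence
#' is summarised by split-R-hat and effective sample size for every
#' parameter; if any split-R-hat reaches 1.01 the run is downgraded to
#' a warning with the report attached, never an error.
#'
#' @param bd a [bayes_data()] (ignored when `prior_only = TRUE`).
#' @param spec an [asymptotic_model_spec()].
#' @param seed integer seed; chains get derived RNG streams.
#' @param prior_only sample the prior instead of the posterior.
#' @param backend "gibbs" (the package sampler) or "jags".
#' @param quiet suppress progress output (JAGS backend only).
#' @return list of class `asymptotic_fit`: `draws` (array
#'   iterations x chains x parameters with named parameters),
#'   `report` (a `convergence_report`), `bd`, `spec`, `seed`.
#' @export
sample_posterior <- function(bd, spec = asymptotic_model_spec(), seed = 1L,
                             prior_only = FALSE,
                             backend = c("gibbs", "jags"), quiet = TRUE) {
  backend <- match.arg(backend)
  stopifnot(inherits(spec, "asymptotic_model_spec"))
  if (!prior_only) stopifnot(inherits(bd, "bayes_data"), length(bd$y) > 0)
  n_keep <- round(spec$iter * (1 - spec$warmup_frac))
  if (backend == "gibbs") {
    pn <- gibbs_param_names(bd, spec)
    draws <- array(NA_real_, dim = c(n_keep, spec$chains, length(pn)),
                   dimnames = list(NULL, NULL, pn))
    for (ch in seq_len(spec$chains))
      draws[, ch, ] <- gibbs_chain(bd, spec,
                                   seed = as.integer(seed) * 100L + ch,
                                   prior_only = prior_only)
  } else {
    draws <- jags_sample(bd, spec, seed, prior_only, quiet)
  }
  report <- convergence_report(draws)
  if (!report$pass)
    warning(sprintf("max split-R-hat %.4f >= 1.01; chains may not have mixed",
                    report$max_rhat))
  structure(list(draws = draws, report = report, bd = bd, spec = spec,
                 seed = seed, backend = backend),
            class = "asymptotic_fit")
}

jags_sample <- function(bd, spec, seed, prior_only = FALSE, quiet = TRUE) {
  ia <- fixed_design(bd, spec, "a"); ic <- fixed_design(bd, spec, "c")
  la <- unique(ia$labels); lc <- unique(ic$labels)
  dat <- list(J = bd$J, Ma = length(la), Mc = length(lc))
  if (!prior_only)
    dat <- c(dat, list(y = bd$y, t = bd$t, sub = bd$sub, sc = bd$sc,
                       ia = ia$idx, ic = ic$idx, N = length(bd$y)))
  inits <- lapply(seq_len(spec$chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) * 100L + ch))
  n_keep <- round(spec$iter * (1 - spec$warmup_frac))
  n_warm <- spec$iter - n_keep
  jm <- rjags::jags.model(textConnection(jags_model_string(spec, prior_only)),
                          data = dat, inits = inits,
                          n.chains = spec$chains, n.adapt = spec$adapt,
                          quiet = quiet)
  update(jm, n_warm, progress.bar = "none")
  mon <- c("a_fix", "c_fix", "sd_a", "sd_b", "sd_c", "sigma",
           "z_a", "z_b", "z_c")
  sm <- rjags::coda.samples(jm, mon, n.iter = n_keep, progress.bar = "none")
  draws <- array(NA_real_, dim = c(n_keep, spec$chains, ncol(sm[[1]])),
                 dimnames = list(NULL, NULL, colnames(sm[[1]])))
  for (ch in seq_len(spec$chains)) draws[, ch, ] <- as.matrix(sm[[ch]])
  dimnames(draws)[[3]] <- relabel_params(colnames(sm[[1]]), la, lc, bd)
  draws
}

# JAGS index names -> readable labels
relabel_params <- function(nm, la, lc, bd) {
  cl4 <- cell4_labels()
  sub_lab <- if (!is.null(bd$subjects)) bd$subjects else
    sprintf("S%03d", seq_len(10000))
  out <- nm
  relab <- function(pat, labels) {
    i <- grep(pat, nm)
    idx <- as.integer(sub(paste0(pat, "\\[(\\d+)\\]"), "\\1", nm[i]))
    out[i] <<- paste0(sub("_fix", "", pat), "[", labels[idx], "]")
  }
  relab("a_fix", la); relab("c_fix", lc)
  for (p in c("sd_a", "sd_b", "sd_c")) {
    i <- grep(paste0("^", p, "\\["), nm)
    idx <- as.integer(sub(".*\\[(\\d+)\\]", "\\1", nm[i]))
    out[i] <- paste0(p, "[", cl4[idx], "]")
  }
  for (p in c("z_a", "z_b", "z_c")) {
    i <- grep(paste0("^", p, "\\["), nm)
    jk <- sub(".*\\[(\\d+),(\\d+)\\]", "\\1 \\2", nm[i])
    j <- as.integer(sub(" .*", "", jk)); k <- as.integer(sub(".* ", "", jk))
    out[i] <- paste0(p, "[", sub_lab[j], ",", cl4[k], "]")
  }
  out
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is halved; R-hat is the classic between/within variance
#' ratio over the resulting 2m half-chains:
#' `sqrt(((n-1)/n W + B/n) / W)`. Returns NaN when every half-chain has
#' zero variance.
#'
#' @param x draws for one parameter: iterations x chains matrix (a
#'   vector is treated as one chain).
#' @return scalar R-hat.
#' @export
split_rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n2 <- floor(nrow(x) / 2)
  if (n2 < 2) stop("need at least 4 iterations")
  halves <- cbind(x[seq_len(n2), , drop = FALSE],
                  x[nrow(x) - n2 + seq_len(n2), , drop = FALSE])
  W <- mean(apply(halves, 2, stats::var))
  B <- n2 * stats::var(colMeans(halves))
  if (W == 0) return(NaN)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Convergence report over all parameters of a draws array
#'
#' @param draws iterations x chains x parameters array.
#' @param threshold pass threshold on split-R-hat (default 1.01).
#' @return list of class `convergence_report`: `table` (parameter,
#'   rhat, ess), `max_rhat`, `pass`.
#' @export
convergence_report <- function(draws, threshold = 1.01) {
  pn <- dimnames(draws)[[3]]
  rhat <- vapply(seq_along(pn), function(p) split_rhat(draws[, , p]),
                 numeric(1))
  ess <- vapply(seq_along(pn), function(p)
    sum(vapply(seq_len(dim(draws)[2]), function(ch)
      unname(coda::effectiveSize(draws[, ch, p])), numeric(1))),
    numeric(1))
  tab <- data.frame(parameter = pn, rhat = rhat, ess = ess,
                    stringsAsFactors = FALSE)
  mx <- max(rhat, na.rm = TRUE)
  structure(list(table = tab, max_rhat = mx,
                 pass = is.finite(mx) && mx < threshold,
                 threshold = threshold),
            class = "convergence_report")
}

#' Pointwise log-likelihood matrix from a fitted model
#'
#' Evaluates, for (optionally thinned) posterior draws, the Normal log
#' likelihood of every observation around its curve value — the
#' draws x observations matrix that WAIC and PSIS-LOO consume.
#'
#' @param fit an `asymptotic_fit`.
#' @param thin keep every `thin`-th draw (default 1 = all).
#' @return matrix, draws x observations.
#' @export
pointwise_loglik <- function(fit, thin = 1L) {
  bd <- fit$bd; spec <- fit$spec
  ia <- fixed_design(bd, spec, "a"); ic <- fixed_design(bd, spec, "c")
  la <- unique(ia$labels); lc <- unique(ic$labels)
  d <- fit$draws
  keep <- seq(1, dim(d)[1], by = thin)
  flat <- matrix(aperm(d[keep, , , drop = FALSE], c(1, 2, 3)),
                 nrow = length(keep) * dim(d)[2], dimnames = list(NULL, NULL))
  colnames(flat) <- dimnames(d)[[3]]
  S <- nrow(flat); N <- length(bd$y)
  cl4 <- cell4_labels()
  a_fix <- flat[, paste0("a[", la, "]"), drop = FALSE]
  c_fix <- flat[, paste0("c[", lc, "]"), drop = FALSE]
  sd_a <- flat[, paste0("sd_a[", cl4, "]"), drop = FALSE]
  sd_b <- flat[, paste0("sd_b[", cl4, "]"), drop = FALSE]
  sd_c <- flat[, paste0("sd_c[", cl4, "]"), drop = FALSE]
  sigma <- flat[, "sigma"]
  zcols <- function(p) flat[, paste0(p, "[", bd$subjects[rep(seq_len(bd$J), each = 4)],
                                     ",", cl4[rep(1:4, bd$J)], "]"), drop = FALSE]
  z_a <- zcols("z_a"); z_b <- zcols("z_b"); z_c <- zcols("z_c")
  jk <- (bd$sub - 1L) * 4L + bd$sc   # column in z matrices per obs
  ll <- matrix(NA_real_, S, N)
  # chunked matrix evaluation keeps memory bounded near chunk x N doubles
  chunk <- max(1L, floor(2e6 / N))
  for (s0 in seq(1, S, by = chunk)) {
    rows <- s0:min(s0 + chunk - 1L, S)
    tmat <- matrix(bd$t - 1, length(rows), N, byrow = TRUE)
    ymat <- matrix(bd$y, length(rows), N, byrow = TRUE)
    ai <- a_fix[rows, ia$idx, drop = FALSE] +
      sd_a[rows, bd$sc, drop = FALSE] * z_a[rows, jk, drop = FALSE]
    bi <- sd_b[rows, bd$sc, drop = FALSE] * z_b[rows, jk, drop = FALSE]
    ci <- c_fix[rows, ic$idx, drop = FALSE] +
      sd_c[rows, bd$sc, drop = FALSE] * z_c[rows, jk, drop = FALSE]
    mu <- ai - (ai - bi) * exp(-exp(ci) * tmat)
    ll[rows, ] <- stats::dnorm(ymat, mu, sigma[rows], log = TRUE)
  }
  ll
}

#' Prior predictive curves
#'
#' Draws (a, c) from their priors with b = 0 and evaluates the
#' asymptotic curve on a time grid — the prior prediction plot's lines.
#'
#' @param spec an [asymptotic_model_spec()].
#' @param n_curves number of prior draws.
#' @param seed integer seed.
#' @param t_grid evaluation grid over the window axis.
#' @return list: `a`, `c` (draws), `t`, `curves` (n_curves x grid matrix).
#' @export
prior_predictive <- function(spec = asymptotic_model_spec(), n_curves = 100,
                             seed = 1L, t_grid = seq(1, 5, by = 0.1)) {
  restore <- local_rng(seed)
  on.exit(restore())
  a <- rnorm(n_curves, spec$prior_a[1], spec$prior_a[2])
  cc <- rnorm(n_curves, spec$prior_c[1], spec$prior_c[2])
  curves <- t(vapply(seq_len(n_curves),
                     function(i) asymptotic_curve(a[i], 0, cc[i], t_grid),
                     numeric(length(t_grid))))
  list(a = a, c = cc, t = t_grid, curves = curves)
}

#' Highest posterior density interval
#'
#' Narrowest contiguous interval containing the requested posterior
#' mass, by sliding a window of ceiling(mass * n) over the sorted
#' sample.
#'
#' @param samples numeric sample (>= 100 values recommended).
#' @param mass interval mass in (0, 1).
#' @return numeric length 2 (lower, upper).
#' @export
hpdi <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  w <- ceiling(mass * n)
  if (w >= n) return(c(x[1], x[n]))
  i <- which.min(x[(w + 1):n] - x[1:(n - w)])
  c(x[i], x[i + w])
}

#' Posterior summary of the fixed effects
#'
#' @param fit an `asymptotic_fit`.
#' @param mass HPDI mass.
#' @return data.frame: parameter, mean, sd, hpdi_lower, hpdi_upper.
#' @export
posterior_summary <- function(fit, mass = 0.95) {
  pn <- grep("^[ac]\\[", dimnames(fit$draws)[[3]], value = TRUE)
  rows <- lapply(pn, function(p) {
    x <- as.vector(fit$draws[, , p])
    h <- hpdi(x, mass)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               hpdi_lower = h[1], hpdi_upper = h[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
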