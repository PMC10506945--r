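#' Nested model family over drug effects
#'
#' From the full model (drug in both the asymptote and the rate design)
#' derives the four nested specifications compared in the study: full,
#' drug on the asymptote only, drug on the rate only, and no drug effect
#' (a and c vary over muscle x emotion only). Priors and random
#' structures are untouched.
#'
#' @param full_spec an [asymptotic_model_spec()] with
#'   `drug_on = c("a", "c")`.
#' @return named list of 4 specs: full, asymptote_only, rate_only,
#'   no_drug.
#' @export
nested_family <- function(full_spec) {
  if (!all(c("a", "c") %in% full_spec$drug_on))
    stop("full_spec must carry drug effects on both a and c")
  variant <- function(on) { s <- full_spec; s$drug_on <- on; s }
  list(full = full_spec,
       asymptote_only = variant("a"),
       rate_only = variant("c"),
       no_drug = variant(character(0)))
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Widely applicable information criterion from pointwise log likelihood
#'
#' Per observation, lppd_i is the log mean over draws of the likelihood
#' (computed stably) and the effective-parameter penalty p_i is the
#' variance over draws of the log likelihood (n - 1 denominator);
#' elpd = sum(lppd_i - p_i) and the criterion is -2 elpd.
#'
#' @param loglik draws x observations matrix.
#' @return list of class `ic_result`: elpd, p_eff, ic, se (of elpd),
#'   pointwise data.frame.
#' @export
waic <- function(loglik) {
  stopifnot(is.matrix(loglik), nrow(loglik) >= 2, ncol(loglik) >= 1)
  if (any(!is.finite(loglik))) stop("non-finite log-likelihood entries")
  S <- nrow(loglik)
  lppd_i <- apply(loglik, 2, logsumexp) - log(S)
  p_i <- apply(loglik, 2, stats::var)
  elpd_i <- lppd_i - p_i
  structure(list(elpd = sum(elpd_i), p_eff = sum(p_i),
                 ic = -2 * sum(elpd_i),
                 se = sqrt(ncol(loglik) * stats::var(elpd_i)),
                 pointwise = data.frame(lppd = lppd_i, p = p_i,
                                        elpd = elpd_i)),
            class = "ic_result")
}

# Generalised Pareto fit (profile-likelihood quantile method of Zhang &
# Stephens 2009) to exceedances x > 0; returns shape k and scale sigma
gpd_fit <- function(x) {
  x <- sort(x); n <- length(x)
  m <- 30L + floor(sqrt(n))
  q1 <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * q1)
  prof <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(prof - prof[j])), numeric(1))
  th_hat <- sum(theta * w)
  # convert to the usual shape convention (xi > 0 = heavy tail)
  k_hat <- mean(log1p(-th_hat * x))
  list(k = k_hat, sigma = -k_hat / th_hat)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Importance ratios for leaving out observation i are the reciprocal
#' pointwise likelihoods; the largest 20% of each observation's ratios
#' are replaced by expected order statistics of a generalised Pareto
#' distribution fitted to them (tail smoothing), truncated at the raw
#' maximum. The fitted tail-shape k is reported per observation and a
#' warning (not an error) is issued when any k exceeds 0.7.
#'
#' @param loglik draws x observations matrix.
#' @param smooth disable to get plain importance-sampling LOO.
#' @param tail_frac fraction of draws treated as the tail (default 0.2).
#' @return `ic_result` with additional `pareto_k` vector; `ic` is the
#'   LOO information criterion -2 elpd_loo.
#' @export
psis_loo <- function(loglik, smooth = TRUE, tail_frac = 0.2) {
  stopifnot(is.matrix(loglik), nrow(loglik) >= 2, ncol(loglik) >= 1)
  if (any(!is.finite(loglik))) stop("non-finite log-likelihood entries")
  S <- nrow(loglik); N <- ncol(loglik)
  elpd_i <- numeric(N); khat <- rep(NA_real_, N)
  M <- ceiling(tail_frac * S)
  for (i in seq_len(N)) {
    lw <- -loglik[, i]
    lw <- lw - max(lw)
    if (smooth && M >= 5 && stats::sd(lw) > 0) {
      ord <- order(lw)
      tail_idx <- ord[(S - M + 1):S]
      cutoff <- exp(lw[ord[S - M]])
      exc <- exp(lw[tail_idx]) - cutoff
      if (max(exc) > 0) {
        fit <- gpd_fit(exc[exc > 0])
        khat[i] <- fit$k
        p <- (seq_len(M) - 0.5) / M
        q <- if (abs(fit$k) < 1e-12) -fit$sigma * log1p(-p)
             else fit$sigma / fit$k * ((1 - p)^(-fit$k) - 1)
        sm <- log(cutoff + q)
        lw[tail_idx] <- pmin(sm, max(lw))
      }
    }
    elpd_i[i] <- logsumexp(lw + loglik[, i]) - logsumexp(lw)
  }
  if (any(khat > 0.7, na.rm = TRUE))
    warning(sum(khat > 0.7, na.rm = TRUE),
            " observation(s) with Pareto k > 0.7; LOO may be unreliable")
  structure(list(elpd = sum(elpd_i), p_eff = NA_real_,
                 ic = -2 * sum(elpd_i),
                 se = sqrt(N * stats::var(elpd_i)),
                 pointwise = data.frame(elpd = elpd_i, k = khat),
                 pareto_k = khat),
            class = "ic_result")
}

#' Information-criterion model weights
#'
#' `w_m = exp(-Delta_m / 2) / sum_k exp(-Delta_k / 2)` with Delta taken
#' from the smallest criterion; invariant to adding a constant to all
#' criteria.
#'
#' @param criteria numeric, one deviance-scale criterion per model.
#' @return weights summing to 1.
#' @export
ic_weights <- function(criteria) {
  if (length(criteria) < 2) stop("need at least 2 models")
  d <- criteria - min(criteria)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit and compare the nested drug-effect model family
#'
#' Samples (or reuses) the four nested models on one dataset, computes
#' WAIC and PSIS-LOO from each model's pointwise log likelihood, and
#' returns the four-row comparison table of normalized weights in the
#' fixed row order Full, Drug effects asymptote only, Drug effects rate
#' only, No effect of drug.
#'
#' @param fits named list of 4 `asymptotic_fit`s (names as returned by
#'   [nested_family()]), all sampled on identical data.
#' @param thin thinning passed to [pointwise_loglik()].
#' @return list of class `model_comparison`: `table` (model,
#'   waic_weight, loo_weight, waic, looic), `ic` (per-model
#'   `ic_result`s).
#' @export
compare_models <- function(fits, thin = 1L) {
  stopifnot(all(c("full", "asymptote_only", "rate_only", "no_drug")
                %in% names(fits)))
  ns <- vapply(fits, function(f) length(f$bd$y), numeric(1))
  if (length(unique(ns)) != 1)
    stop("models were fitted on different observation counts")
  ord <- c("full", "asymptote_only", "rate_only", "no_drug")
  ics <- lapply(fits[ord], function(f) {
    ll <- pointwise_loglik(f, thin = thin)
    list(waic = waic(ll), loo = suppressWarnings(psis_loo(ll)))
  })
  waic_v <- vapply(ics, function(x) x$waic$ic, numeric(1))
  loo_v <- vapply(ics, function(x) x$loo$ic, numeric(1))
  tab <- data.frame(
    model = c("Full", "Drug effects asymptote only",
              "Drug effects rate only", "No effect of drug"),
    waic_weight = ic_weights(waic_v),
    loo_weight = ic_weights(loo_v),
    waic = waic_v, looic = loo_v,
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, ic = ics), class = "model_comparison")
}

#' Sample all four nested models on one dataset
#'
#' @param bd a [bayes_data()].
#' @param full_spec the full-model spec.
#' @param seed integer seed (each model gets a derived stream).
#' @param quiet suppress sampler output.
#' @return named list of `asymptotic_fit`s.
#' @export
fit_nested_family <- function(bd, full_spec = asymptotic_model_spec(),
                              seed = 1L, quiet = TRUE) {
  fam <- nested_family(full_spec)
  out <- vector("list", length(fam)); names(out) <- names(fam)
  for (i in seq_along(fam))
    out[[i]] <- suppressWarnings(
      sample_posterior(bd, fam[[i]], seed = seed + 13L * i, quiet = quiet))
  out
}
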