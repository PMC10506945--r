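# Blocked Gibbs / Metropolis sampler for the hierarchical asymptotic
# model. Given the rate side (c), the curve is linear in the asymptote
# and starting-value parameters, so a_fix, z_a, z_b, sd_a, sd_b have
# exact Gaussian (or truncated-Gaussian) full conditionals. The rate
# side (c_fix, z_c) uses vectorised Metropolis updates with the
# conditionally Gaussian partner block analytically marginalised
# (partially collapsed, via rank-1 Sherman-Morrison marginal
# likelihoods), each followed by a conjugate redraw of that block;
# sd_c uses plain Metropolis and the residual SD 1-d slice sampling.
# Two families of interweaving moves target the slow directions that
# defeat single-site samplers:
#   * translation: (fix[m], z[G,k]) -> (fix[m] + s*e, z[G,k] - e);
#     the likelihood is invariant and the prior conditional in e is
#     Gaussian, so the move is an exact Gibbs draw along the direction;
#   * scale: (sd[k], z[,k]) -> (e^h sd[k], e^-h z[,k]), a group move
#     with Jacobian e^{h(1-J)}, Metropolis-accepted on the priors.
# Step sizes adapt during warmup only and are frozen afterwards, so the
# post-warmup kernel is a fixed, valid MCMC kernel.

# group sums over all levels 1..nlev, including empty groups
gsum <- function(x, idx, nlev) {
  out <- numeric(nlev)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s
  }
  out
}

# draw from N(mean, sd) truncated to [0, Inf); works in the upper-tail
# complement so far-negative conditional means stay accurate
rtruncnorm_pos <- function(n, mean, sd) {
  q_hi <- stats::pnorm(0, mean, sd, lower.tail = FALSE)
  u <- pmax(q_hi * stats::runif(n), 1e-300)
  mean - sd * stats::qnorm(u)
}

# static problem description shared by all sweeps of one chain
gibbs_problem <- function(bd, spec, prior_only = FALSE) {
  J <- bd$J
  drug_a <- "a" %in% spec$drug_on
  drug_c <- "c" %in% spec$drug_on
  Ma <- if (drug_a) 12L else 4L
  Mc <- if (drug_c) 12L else 4L
  if (prior_only) {
    y <- numeric(0); tt <- numeric(0); sub <- integer(0); sc <- integer(0)
    ia <- integer(0); ic <- integer(0)
  } else {
    y <- bd$y; tt <- bd$t; sub <- bd$sub; sc <- bd$sc
    ia <- if (drug_a) bd$cell12 else bd$sc
    ic <- if (drug_c) bd$cell12 else bd$sc
  }
  group_of <- function(M) lapply(seq_len(M), function(m) {
    if (M == 4L) seq_len(J)
    else which(bd$sub_drug == ((m - 1L) %/% 4L) + 1L)
  })
  list(J = J, Ma = Ma, Mc = Mc, y = y, tt = tt, sub = sub, sc = sc,
       ia = ia, ic = ic, N = length(y),
       # column-major site index so z[jk] linear indexing agrees with
       # the J x 4 matrix layout (row = subject, column = cell)
       jk = (sc - 1L) * J + sub, njk = J * 4L,
       grp_a = group_of(Ma), grp_c = group_of(Mc),
       pa_m = spec$prior_a[1], pa_v = spec$prior_a[2]^2,
       pc_m = spec$prior_c[1], pc_v = spec$prior_c[2]^2,
       psd_v = spec$prior_re_sd^2, psig_v = spec$prior_sigma^2)
}

gibbs_init <- function(pr, spec) {
  list(a_fix = rep(pr$pa_m, pr$Ma), c_fix = rep(pr$pc_m, pr$Mc),
       z_a = matrix(0, pr$J, 4), z_b = matrix(0, pr$J, 4),
       z_c = matrix(0, pr$J, 4),
       sd_a = rep(spec$prior_re_sd / 2, 4),
       sd_b = rep(spec$prior_re_sd / 2, 4),
       sd_c = rep(spec$prior_re_sd / 2, 4),
       sigma = if (pr$N) stats::sd(pr$y) else spec$prior_sigma / 2)
}

gibbs_steps_init <- function(pr) {
  list(cfix = rep(0.2, pr$Mc), zc = rep(0.4, pr$njk), sdc = rep(0.1, 4),
       scale = matrix(0.3, 3, 4))
}

# one full sweep; returns list(state, acc); `moves` allows switching
# off move families (used by the correctness tests)
gibbs_sweep <- function(st, pr, steps,
                        moves = c("base", "translate", "scale")) {
  with_pr <- function(nm) pr[[nm]]
  J <- pr$J; N <- pr$N; njk <- pr$njk
  y <- pr$y; tt <- pr$tt; sc <- pr$sc; ia <- pr$ia; ic <- pr$ic
  jk <- pr$jk
  acc <- list(cfix = rep(0, pr$Mc), zc = rep(0, njk), sdc = rep(0, 4),
              scale = matrix(0, 3, 4))
  a_fix <- st$a_fix; c_fix <- st$c_fix
  z_a <- st$z_a; z_b <- st$z_b; z_c <- st$z_c
  sd_a <- st$sd_a; sd_b <- st$sd_b; sd_c <- st$sd_c; sigma <- st$sigma

  cur_c <- function() c_fix[ic] + sd_c[sc] * z_c[jk]
  cur_w <- function(cv) exp(-exp(cv) * (tt - 1))

  if (N == 0) {
    # prior-only: every block reduces to its prior
    a_fix <- stats::rnorm(pr$Ma, pr$pa_m, sqrt(pr$pa_v))
    c_fix <- stats::rnorm(pr$Mc, pr$pc_m, sqrt(pr$pc_v))
    z_a[] <- stats::rnorm(njk); z_b[] <- stats::rnorm(njk)
    z_c[] <- stats::rnorm(njk)
    sd_a <- abs(stats::rnorm(4, 0, sqrt(pr$psd_v)))
    sd_b <- abs(stats::rnorm(4, 0, sqrt(pr$psd_v)))
    sd_c <- abs(stats::rnorm(4, 0, sqrt(pr$psd_v)))
    sigma <- abs(stats::rnorm(1, 0, sqrt(pr$psig_v)))
    return(list(state = list(a_fix = a_fix, c_fix = c_fix, z_a = z_a,
                             z_b = z_b, z_c = z_c, sd_a = sd_a,
                             sd_b = sd_b, sd_c = sd_c, sigma = sigma),
                acc = acc))
  }

  sig2 <- sigma^2
  cv <- cur_c(); w <- cur_w(cv); p <- 1 - w
  bv <- sd_b[sc] * z_b[jk]

  # marginal (collapsed) log likelihood per group for y = coef*x + r + e
  # with latent x ~ N(0, v_g): rank-1 Sherman-Morrison form
  lml <- function(r, coef, v_g, grp, ng) {
    S2 <- gsum(coef^2, grp, ng)
    Sr <- gsum(coef * r, grp, ng)
    SS <- gsum(r^2, grp, ng)
    -0.5 * (log1p(v_g * S2 / sig2) +
              (SS - v_g * Sr^2 / (sig2 + v_g * S2)) / sig2)
  }
  va_site <- sd_a[((seq_len(njk) - 1L) %/% J) + 1L]^2

  if ("base" %in% moves) {
    # two sub-sweeps of the collapsed c-side updates, each followed by
    # a conjugate redraw of the marginalised block
    for (rep_c in 1:2) {
      # --- c_fix: Metropolis with a_fix analytically marginalised
      za_v <- sd_a[sc] * z_a[jk]
      prop <- stats::rnorm(pr$Mc, 0, steps$cfix)
      w2 <- cur_w(cv + prop[ic])
      r1 <- y - (za_v + pr$pa_m) * p - bv * w
      r2 <- y - (za_v + pr$pa_m) * (1 - w2) - bv * w2
      dll <- lml(r2, 1 - w2, rep(pr$pa_v, pr$Mc), ic, pr$Mc) -
        lml(r1, p, rep(pr$pa_v, pr$Mc), ic, pr$Mc)
      dlp <- -((c_fix + prop - pr$pc_m)^2 - (c_fix - pr$pc_m)^2) /
        (2 * pr$pc_v)
      a_ok <- log(stats::runif(pr$Mc)) < dll + dlp
      c_fix <- c_fix + prop * a_ok
      acc$cfix <- acc$cfix + a_ok
      cv <- cur_c(); w <- cur_w(cv); p <- 1 - w

      # --- a_fix | rest (conjugate redraw after the collapsed move)
      r <- y - bv * w - (sd_a[sc] * z_a[jk]) * p
      prec <- 1 / pr$pa_v + gsum(p^2, ia, pr$Ma) / sig2
      mean_ <- (pr$pa_m / pr$pa_v + gsum(p * r, ia, pr$Ma) / sig2) / prec
      a_fix <- stats::rnorm(pr$Ma, mean_, sqrt(1 / prec))

      # --- z_c: Metropolis with the site's z_a marginalised
      prop <- stats::rnorm(njk, 0, steps$zc)
      w2 <- cur_w(cv + (sd_c[sc] * prop[jk]))
      r1 <- y - a_fix[ia] * p - bv * w
      r2 <- y - a_fix[ia] * (1 - w2) - bv * w2
      dll <- lml(r2, 1 - w2, va_site, jk, njk) - lml(r1, p, va_site, jk, njk)
      dlp <- -((as.vector(z_c) + prop)^2 - as.vector(z_c)^2) / 2
      a_ok <- log(stats::runif(njk)) < dll + dlp
      z_c[] <- as.vector(z_c) + prop * a_ok
      acc$zc <- acc$zc + a_ok
      cv <- cur_c(); w <- cur_w(cv); p <- 1 - w

      # --- z_a | rest (conjugate redraw)
      g <- sd_a[sc] * p
      r <- y - a_fix[ia] * p - bv * w
      prec <- 1 + gsum(g^2, jk, njk) / sig2
      mean_ <- (gsum(g * r, jk, njk) / sig2) / prec
      z_a[] <- stats::rnorm(njk, mean_, sqrt(1 / prec))
    }
    av <- a_fix[ia] + sd_a[sc] * z_a[jk]

    # --- z_b | rest
    h <- sd_b[sc] * w
    r <- y - av * p
    prec <- 1 + gsum(h^2, jk, njk) / sig2
    mean_ <- (gsum(h * r, jk, njk) / sig2) / prec
    z_b[] <- stats::rnorm(njk, mean_, sqrt(1 / prec))
    bv <- sd_b[sc] * z_b[jk]

    # --- sd_a | rest (truncated-normal conjugate)
    u <- z_a[jk] * p
    r <- y - a_fix[ia] * p - bv * w
    prec <- 1 / pr$psd_v + gsum(u^2, sc, 4) / sig2
    mean_ <- (gsum(u * r, sc, 4) / sig2) / prec
    sd_a <- rtruncnorm_pos(4, mean_, sqrt(1 / prec))
    av <- a_fix[ia] + sd_a[sc] * z_a[jk]

    # --- sd_b | rest
    u <- z_b[jk] * w
    r <- y - av * p
    prec <- 1 / pr$psd_v + gsum(u^2, sc, 4) / sig2
    mean_ <- (gsum(u * r, sc, 4) / sig2) / prec
    sd_b <- rtruncnorm_pos(4, mean_, sqrt(1 / prec))
    bv <- sd_b[sc] * z_b[jk]

    # --- sigma | rest (slice on log sigma; the sum of squares is fixed)
    mu <- av * p + bv * w
    SS <- sum((y - mu)^2)
    lf <- function(ls) -N * ls - SS / (2 * exp(2 * ls)) -
      exp(2 * ls) / (2 * pr$psig_v)
    ls0 <- log(sigma)
    lev <- lf(ls0) - stats::rexp(1)
    lo <- ls0 - 1; hi <- ls0 + 1
    while (lf(lo) > lev) lo <- lo - 1
    while (lf(hi) > lev) hi <- hi + 1
    repeat {
      ls1 <- stats::runif(1, lo, hi)
      if (lf(ls1) > lev) break
      if (ls1 < ls0) lo <- ls1 else hi <- ls1
    }
    sigma <- exp(ls1); sig2 <- sigma^2

    # --- sd_c | rest (Metropolis per cell column)
    prop <- sd_c + stats::rnorm(4, 0, steps$sdc)
    ok <- prop > 0
    if (any(ok)) {
      sd2 <- ifelse(ok, prop, sd_c)
      w2 <- cur_w(c_fix[ic] + sd2[sc] * z_c[jk])
      mu2 <- av * (1 - w2) + bv * w2
      mu <- av * p + bv * w
      dll <- gsum(((y - mu2)^2 - (y - mu)^2), sc, 4) / (-2 * sig2)
      dlp <- -(sd2^2 - sd_c^2) / (2 * pr$psd_v)
      a_ok <- ok & (log(stats::runif(4)) < dll + dlp)
      sd_c <- ifelse(a_ok, prop, sd_c)
      acc$sdc <- acc$sdc + a_ok
      cv <- cur_c(); w <- cur_w(cv); p <- 1 - w
    }
  }

  if ("translate" %in% moves) {
    # exact Gibbs along the likelihood-invariant translation directions
    for (m in seq_len(pr$Ma)) {
      G <- pr$grp_a[[m]]; k <- if (pr$Ma == 12L) ((m - 1L) %% 4L) + 1L else m
      s <- sd_a[k]; n_G <- length(G)
      D <- s^2 / pr$pa_v + n_G
      br <- (sum(z_a[G, k]) - (a_fix[m] - pr$pa_m) * s / pr$pa_v) / D +
        stats::rnorm(1) / sqrt(D)
      a_fix[m] <- a_fix[m] + s * br
      z_a[G, k] <- z_a[G, k] - br
    }
    for (m in seq_len(pr$Mc)) {
      G <- pr$grp_c[[m]]; k <- if (pr$Mc == 12L) ((m - 1L) %% 4L) + 1L else m
      s <- sd_c[k]; n_G <- length(G)
      D <- s^2 / pr$pc_v + n_G
      br <- (sum(z_c[G, k]) - (c_fix[m] - pr$pc_m) * s / pr$pc_v) / D +
        stats::rnorm(1) / sqrt(D)
      c_fix[m] <- c_fix[m] + s * br
      z_c[G, k] <- z_c[G, k] - br
    }
  }

  if ("scale" %in% moves) {
    # group move on (sd, z) per column: (sd, z) -> (e^h sd, e^-h z)
    for (pi in 1:3) {
      zmat <- switch(pi, z_a, z_b, z_c)
      sdv <- switch(pi, sd_a, sd_b, sd_c)
      for (k in 1:4) {
        eta <- stats::rnorm(1, 0, steps$scale[pi, k])
        ssq <- sum(zmat[, k]^2)
        la <- -(exp(2 * eta) - 1) * sdv[k]^2 / (2 * pr$psd_v) -
          (exp(-2 * eta) - 1) * ssq / 2 + eta * (1 - J)
        if (log(stats::runif(1)) < la) {
          sdv[k] <- sdv[k] * exp(eta)
          zmat[, k] <- zmat[, k] * exp(-eta)
          acc$scale[pi, k] <- acc$scale[pi, k] + 1
        }
      }
      switch(pi, { z_a <- zmat; sd_a <- sdv },
                 { z_b <- zmat; sd_b <- sdv },
                 { z_c <- zmat; sd_c <- sdv })
    }
  }

  list(state = list(a_fix = a_fix, c_fix = c_fix, z_a = z_a, z_b = z_b,
                    z_c = z_c, sd_a = sd_a, sd_b = sd_b, sd_c = sd_c,
                    sigma = sigma),
       acc = acc)
}

flatten_state <- function(st) {
  c(st$a_fix, st$c_fix, st$sd_a, st$sd_b, st$sd_c, st$sigma,
    as.vector(t(st$z_a)), as.vector(t(st$z_b)), as.vector(t(st$z_c)))
}

# one chain; returns kept draws as matrix iterations x parameters
gibbs_chain <- function(bd, spec, seed, prior_only = FALSE,
                        moves = c("base", "translate", "scale")) {
  restore <- local_rng(seed)
  on.exit(restore())
  pr <- gibbs_problem(bd, spec, prior_only)
  st <- gibbs_init(pr, spec)
  steps <- gibbs_steps_init(pr)
  n_keep <- round(spec$iter * (1 - spec$warmup_frac))
  n_warm <- spec$iter - n_keep
  keep <- matrix(NA_real_, n_keep, pr$Ma + pr$Mc + 12 + 1 + 3 * pr$njk)
  acc_tot <- NULL
  batch <- 0L
  for (it in seq_len(spec$iter)) {
    sw <- gibbs_sweep(st, pr, steps, moves)
    st <- sw$state
    acc_tot <- if (is.null(acc_tot)) sw$acc else
      Map(function(a, b) a + b, acc_tot, sw$acc)
    if (it <= n_warm && it %% 50L == 0L) {
      # warmup step-size adaptation toward ~0.44 acceptance, frozen
      # after warmup (the c-side runs two proposals per sweep)
      batch <- batch + 1L
      g <- min(0.5, 1 / sqrt(batch))
      steps$cfix <- steps$cfix * exp(g * (acc_tot$cfix / 100 - 0.44))
      steps$zc <- steps$zc * exp(g * (acc_tot$zc / 100 - 0.44))
      steps$sdc <- steps$sdc * exp(g * (acc_tot$sdc / 50 - 0.44))
      steps$scale <- steps$scale * exp(g * (acc_tot$scale / 50 - 0.44))
      acc_tot <- NULL
    }
    if (it > n_warm) keep[it - n_warm, ] <- flatten_state(st)
  }
  keep
}

gibbs_param_names <- function(bd, spec) {
  drug_a <- "a" %in% spec$drug_on
  drug_c <- "c" %in% spec$drug_on
  la <- if (drug_a) bd$cells12 else bd$cells4
  lc <- if (drug_c) bd$cells12 else bd$cells4
  cl4 <- cell4_labels()
  zl <- function(p) paste0(p, "[", rep(bd$subjects, each = 4), ",",
                           rep(cl4, bd$J), "]")
  c(paste0("a[", la, "]"), paste0("c[", lc, "]"),
    paste0("sd_a[", cl4, "]"), paste0("sd_b[", cl4, "]"),
    paste0("sd_c[", cl4, "]"), "sigma",
    zl("z_a"), zl("z_b"), zl("z_c"))
}
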