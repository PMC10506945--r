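#' Fit a linear mixed model with a documented reduction ladder
#'
#' Fits by restricted likelihood (REML) with Satterthwaite denominator
#' df for the Type-III F table. `ladder` is an ordered character vector
#' of random-effect structures (full formulas' RHS random parts); the
#' first entry is the maximal structure, and on a convergence failure
#' the next entry is tried, recording how far the ladder was descended.
#' Singular fits (a variance component estimated at zero) are accepted
#' as converged, as is standard for these designs.
#'
#' @param fixed fixed-effects formula, e.g. `log_emg ~ emotion*drug*time_c`.
#' @param ladder character vector of random-effect terms, e.g.
#'   `"(1 + emotion*time_c | subject) + (1 | stimulus)"`.
#' @param data model data.
#' @param reml use REML (default TRUE).
#' @return list of class `lmm_fit`: `model` (merMod), `anova` (Type-III
#'   Satterthwaite F table), `coefficients`, `varcor`, `formula`,
#'   `reduction_step` (1 = maximal), `converged`.
#' @export
fit_lmm <- function(fixed, ladder, data, reml = TRUE) {
  terms_fixed <- attr(stats::terms(fixed), "term.labels")
  for (v in all.vars(fixed))
    if (!v %in% names(data)) stop("column not in data: ", v)
  last_err <- NULL
  for (step in seq_along(ladder)) {
    f <- stats::as.formula(paste(deparse(fixed), "+", ladder[step]))
    try_opt <- function(ctrl) {
      msgs <- character(0)
      m <- withCallingHandlers(
        lmerTest::lmer(f, data = data, REML = reml, control = ctrl),
        warning = function(w) {
          msgs <<- c(msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      conv <- m@optinfo$conv$lme4
      if (!is.null(conv$code) && conv$code < 0) stop("optimizer failure")
      if (any(grepl("failed to converge|unable to evaluate", msgs,
                    ignore.case = TRUE)))
        stop("convergence warning: ", paste(msgs, collapse = "; "))
      m
    }
    # retry with bobyqa at a larger evaluation budget before declaring
    # this random structure unfit
    fit <- tryCatch(
      try_opt(lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e1) tryCatch(
        try_opt(lme4::lmerControl(
          check.conv.singular = "ignore", optimizer = "bobyqa",
          optCtrl = list(maxfun = 1e5))),
        error = function(e2) e2))
    if (!inherits(fit, "error")) {
      atab <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
      return(structure(list(model = fit,
                            anova = as.data.frame(atab),
                            coefficients = summary(fit)$coefficients,
                            varcor = lme4::VarCorr(fit),
                            formula = f,
                            reduction_step = step,
                            converged = TRUE),
                       class = "lmm_fit"))
    }
    last_err <- fit
  }
  stop("no model on the reduction ladder converged: ",
       conditionMessage(last_err))
}

# random-structure ladders, maximal first; correlations dropped first,
# then the interaction slope, then the time slope
emg_ladder <- function(by_stim_emotion = FALSE) {
  stim <- if (by_stim_emotion) "(1 + emotion | stimulus)" else "(1 | stimulus)"
  c(paste("(1 + emotion * time_c | subject) +", stim),
    paste("(1 + emotion * time_c || subject) +", stim),
    paste("(1 + emotion + time_c || subject) +", stim),
    paste("(1 + emotion || subject) +", stim),
    paste("(1 | subject) +", stim))
}

#' Frequentist LMM of binned log EMG for one muscle
#'
#' One model per muscle: fixed effects emotion x drug x time (time as a
#' numeric covariate over the five 1-s windows, optionally centred),
#' random intercepts by subject and by stimulus face, and by-subject
#' random slopes for emotion, time, and their interaction (reduced along
#' the documented ladder only if the fit fails).
#'
#' @param binned the `binned` table of [preprocess_emg()] (or
#'   [simulate_binned()] output).
#' @param muscle "ZM" or "CS".
#' @param center_time centre the window covariate (default TRUE).
#' @param by_stim_emotion also give stimulus faces an emotion slope.
#' @param ladder override the random-structure ladder.
#' @return an `lmm_fit`.
#' @export
fit_emg_lmm <- function(binned, muscle = c("ZM", "CS"), center_time = TRUE,
                        by_stim_emotion = FALSE, ladder = NULL) {
  muscle <- match.arg(muscle)
  d <- binned[binned$muscle == muscle, , drop = FALSE]
  stopifnot(nrow(d) > 0)
  d <- prep_lmm_data(d, center_time)
  if (is.null(ladder)) ladder <- emg_ladder(by_stim_emotion)
  fit_lmm(log_emg ~ emotion * drug * time_c, ladder, d)
}

prep_lmm_data <- function(d, center_time = TRUE) {
  d$emotion <- factor(d$emotion, levels = EMOTION_LEVELS)
  d$drug <- factor(d$drug, levels = DRUG_LEVELS)
  d$subject <- factor(d$subject)
  d$stimulus <- factor(d$stimulus)
  d$time_c <- if (center_time) d$window - 3 else d$window
  contrasts(d$emotion) <- stats::contr.sum(2)
  contrasts(d$drug) <- stats::contr.sum(3)
  d
}

#' Simple slopes of log EMG over time, per emotion
#'
#' Follow-up per-emotion refits of one muscle's time course: the linear
#' trend of log EMG per window with by-subject time slopes and stimulus
#' intercepts. z is the Wald ratio b/SE.
#'
#' @inheritParams fit_emg_lmm
#' @return data.frame: emotion, b (per window), SE, z, p.
#' @export
simple_slopes <- function(binned, muscle = c("ZM", "CS")) {
  muscle <- match.arg(muscle)
  out <- lapply(EMOTION_LEVELS, function(e) {
    d <- binned[binned$muscle == muscle & binned$emotion == e, , drop = FALSE]
    d <- prep_lmm_data(d, center_time = TRUE)
    fit <- fit_lmm(log_emg ~ time_c,
                   c("(1 + time_c | subject) + (1 | stimulus)",
                     "(1 + time_c || subject) + (1 | stimulus)",
                     "(1 | subject) + (1 | stimulus)"),
                   d)
    co <- fit$coefficients["time_c", ]
    z <- co[["Estimate"]] / co[["Std. Error"]]
    data.frame(emotion = e, b = co[["Estimate"]], SE = co[["Std. Error"]],
               z = z, p = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Frequentist LMM of z-scored response times
#'
#' Fixed effects emotion x drug; random by-subject and by-stimulus
#' intercepts and emotion slopes.
#'
#' @param rt_prepared output of [prepare_rt()]; flagged outlier trials
#'   are dropped here.
#' @return an `lmm_fit`.
#' @export
rt_lmm <- function(rt_prepared) {
  d <- rt_prepared[!rt_prepared$outlier, , drop = FALSE]
  d <- data.frame(rt_z = d$rt_z,
                  emotion = factor(d$emotion, levels = EMOTION_LEVELS),
                  drug = factor(d$drug, levels = DRUG_LEVELS),
                  subject = factor(d$subject_id),
                  stimulus = factor(d$stimulus_face_id))
  contrasts(d$emotion) <- stats::contr.sum(2)
  contrasts(d$drug) <- stats::contr.sum(3)
  fit_lmm(rt_z ~ emotion * drug,
          c("(1 + emotion | subject) + (1 + emotion | stimulus)",
            "(1 + emotion || subject) + (1 + emotion || stimulus)",
            "(1 + emotion || subject) + (1 | stimulus)",
            "(1 | subject) + (1 | stimulus)"),
          d)
}
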