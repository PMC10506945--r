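#' Filter specification for surface EMG
#'
#' The analysis chain is band-pass, 50 Hz notch, full-wave
#' rectification, then low-pass smoothing of the rectified signal.
#' Filters are 4th-order Butterworth sections applied zero-phase
#' (forward-backward); the notch is a 2nd-order IIR biquad with quality
#' factor `notch_q` (Q = 30 is about 1.7 Hz of -3 dB width).
#'
#' @param bp_low,bp_high band-pass edges, Hz.
#' @param notch line-interference frequency, Hz.
#' @param smooth_low low-pass edge applied after rectification, Hz.
#' @param order Butterworth order of the band-pass and low-pass.
#' @param notch_q notch quality factor.
#' @param zero_phase apply filters forward-backward (filtfilt).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(bp_low = 20, bp_high = 400, notch = 50,
                        smooth_low = 40, order = 4, notch_q = 30,
                        zero_phase = TRUE) {
  if (!(0 < bp_low && bp_low < smooth_low && smooth_low < bp_high))
    stop("need 0 < bp_low < smooth_low < bp_high")
  structure(list(bp_low = bp_low, bp_high = bp_high, notch = notch,
                 smooth_low = smooth_low, order = order,
                 notch_q = notch_q, zero_phase = zero_phase),
            class = "filter_spec")
}

#' Desk-scale filter specification
#'
#' At the desk profile's 600 Hz sampling rate the full-scale 400 Hz
#' band-pass edge would sit above Nyquist, so the upper edge is moved to
#' 250 Hz; all other stages are unchanged.
#'
#' @param ... overrides passed to [filter_spec()].
#' @return A `filter_spec`.
#' @export
desk_filter_spec <- function(...) {
  args <- list(bp_high = 250)
  args[names(list(...))] <- list(...)
  do.call(filter_spec, args)
}

# biquad notch coefficients (b, a) for f0 at sampling rate fs
notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

apply_filt <- function(flt, x, zero_phase) {
  if (zero_phase) signal::filtfilt(flt, x) else signal::filter(flt, x)
}

#' Linear (pre-rectification) filtering stages
#'
#' Band-pass plus notch, without rectification or smoothing. Exposed
#' separately because these stages are linear: applied to a sum of
#' signals they equal the sum of the filtered parts.
#'
#' @param x numeric signal, microvolt.
#' @param fs sampling rate, Hz.
#' @param spec a [filter_spec()].
#' @return filtered signal, same length as `x`.
#' @export
filter_linear <- function(x, fs, spec = filter_spec()) {
  if (fs / 2 <= spec$bp_high)
    stop("sampling rate too low for the requested band-pass edge")
  stopifnot(is.numeric(x), length(x) > 12 * spec$order)
  bp <- signal::butter(spec$order, c(spec$bp_low, spec$bp_high) / (fs / 2),
                       type = "pass")
  y <- apply_filt(bp, x, spec$zero_phase)
  nc <- notch_coefs(spec$notch, fs, spec$notch_q)
  apply_filt(signal::Arma(b = nc$b, a = nc$a), y, spec$zero_phase)
}

#' Full EMG filter chain: band-pass, notch, rectify, smooth
#'
#' Fixed order of operations: band-pass -> notch -> full-wave
#' rectification -> low-pass of the rectified signal. The output is the
#' non-negative amplitude envelope (up to small filter ringing).
#'
#' @inheritParams filter_linear
#' @return envelope, same length as `x`.
#' @export
filter_chain <- function(x, fs, spec = filter_spec()) {
  y <- abs(filter_linear(x, fs, spec))
  lp <- signal::butter(spec$order, spec$smooth_low / (fs / 2), type = "low")
  apply_filt(lp, y, spec$zero_phase)
}

#' Epoch an envelope and normalise to baseline
#'
#' Extracts the epoch from `epoch_pre` s before to `epoch_post` s after
#' stimulus onset and divides by the mean envelope of the 0.5-s window
#' immediately preceding onset, giving the proportion-of-baseline scale
#' on which 1 means 100% of baseline.
#'
#' @param envelope output of [filter_chain()] covering the epoch.
#' @param fs sampling rate, Hz.
#' @param onset_sample index of stimulus onset (t = 0) in `envelope`.
#' @param epoch_pre,epoch_post epoch extent, s.
#' @param baseline_window length of the pre-onset baseline, s.
#' @param eps smallest admissible baseline mean, microvolt.
#' @return list: `values` (proportion of baseline over the epoch),
#'   `baseline_mean` (microvolt), `time` (s relative to onset).
#' @export
epoch_and_normalize <- function(envelope, fs, onset_sample,
                                epoch_pre = 0.5, epoch_post = 5,
                                baseline_window = 0.5, eps = 1e-6) {
  n_pre <- round(epoch_pre * fs); n_post <- round(epoch_post * fs)
  n_base <- round(baseline_window * fs)
  if (onset_sample - n_pre < 1 || onset_sample + n_post > length(envelope))
    stop("envelope does not cover the requested epoch")
  base <- mean(envelope[(onset_sample - n_base):(onset_sample - 1L)])
  if (!is.finite(base) || base <= eps)
    stop("degenerate (near-zero) baseline; cannot normalise")
  idx <- (onset_sample - n_pre):(onset_sample + n_post)
  list(values = envelope[idx] / base,
       baseline_mean = base,
       time = (idx - onset_sample) / fs)
}

#' Two-SD outlier-trial detection
#'
#' Applies, per subject and muscle, the 2-SD rejection rules to
#' per-trial summaries of the normalised epoch: a trial is flagged by
#' the mean rule if its epoch mean lies more than 2 SDs from the mean of
#' trial means, by the peak rule if its epoch peak lies more than 2 SDs
#' from the mean peak, and by the baseline rule if either statistic of
#' its baseline segment does the same. SDs are computed in a single pass
#' including the candidate trial; comparisons are strict. Rules combine
#' by union by default (`rule = "union"`); `rule = "intersection"`
#' requires mean and peak rule to agree before a trial is excluded
#' (the baseline rule always excludes on its own).
#'
#' @param stats data.frame with one row per trial x muscle and columns
#'   subject, muscle, trial_index, mean_val, peak_val, base_mean,
#'   base_peak (see [epoch_stats()]).
#' @param rule "union" or "intersection" combination of mean/peak rules.
#' @param k SD multiplier (default 2).
#' @return list of class `outlier_report`: `flags` (the input plus
#'   logical columns mean_rule, peak_rule, baseline_rule, excluded) and
#'   `excluded_fraction`.
#' @export
detect_outlier_trials <- function(stats, rule = c("union", "intersection"),
                                  k = 2) {
  rule <- match.arg(rule)
  need <- c("subject", "muscle", "trial_index", "mean_val", "peak_val",
            "base_mean", "base_peak")
  stopifnot(all(need %in% names(stats)))
  grp <- interaction(stats$subject, stats$muscle, drop = TRUE)
  if (min(table(grp)) < 3)
    stop("need at least 3 trials per subject x muscle for 2-SD rejection")
  out_rule <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    if (s == 0) rep(FALSE, length(x)) else abs(x - m) > k * s
  }
  by_grp <- function(col) as.vector(unsplit(lapply(split(stats[[col]], grp),
                                                   out_rule), grp))
  mean_rule <- by_grp("mean_val")
  peak_rule <- by_grp("peak_val")
  baseline_rule <- by_grp("base_mean") | by_grp("base_peak")
  excluded <- if (rule == "union") mean_rule | peak_rule | baseline_rule
              else (mean_rule & peak_rule) | baseline_rule
  flags <- cbind(stats, mean_rule = mean_rule, peak_rule = peak_rule,
                 baseline_rule = baseline_rule, excluded = excluded)
  structure(list(flags = flags,
                 excluded_fraction = mean(excluded),
                 rule = rule, k = k),
            class = "outlier_report")
}

#' Per-trial summary statistics of a normalised epoch
#'
#' @param ep output of [epoch_and_normalize()].
#' @return one-row data.frame: mean_val, peak_val (post-onset epoch) and
#'   base_mean, base_peak (pre-onset segment), on the proportion scale.
#' @export
epoch_stats <- function(ep) {
  post <- ep$values[ep$time >= 0]
  pre <- ep$values[ep$time < 0]
  data.frame(mean_val = mean(post), peak_val = max(post),
             base_mean = mean(pre), base_peak = max(pre))
}

#' Bin a normalised epoch into five 1-s log windows
#'
#' Windows are half-open `[w-1, w)` seconds after onset, `w = 1..5`; the
#' window mean proportion of baseline is floored at `epsilon_floor` and
#' natural-log transformed.
#'
#' @param ep output of [epoch_and_normalize()].
#' @param epsilon_floor lower floor on the window mean proportion.
#' @return numeric length 5, `log_emg` per window.
#' @export
bin_log_windows <- function(ep, epsilon_floor = 1e-4) {
  vapply(1:5, function(w) {
    v <- ep$values[ep$time >= (w - 1) & ep$time < w]
    log(max(mean(v), epsilon_floor))
  }, numeric(1))
}

#' Preprocess a simulated (or loaded) EMG dataset
#'
#' Runs every trial and muscle through [filter_chain()],
#' [epoch_and_normalize()], the 2-SD outlier rules, and
#' [bin_log_windows()], returning the analysis-ready long table of log
#' proportion-of-baseline window means plus the outlier report.
#'
#' @param sim an `emg_simulation` (or a list with the same fields).
#' @param spec a [filter_spec()]; defaults to the spec matching the
#'   simulation's sampling rate.
#' @param rule outlier rule combination, see [detect_outlier_trials()].
#' @return list of class `emg_preprocessed`: `binned` (data.frame
#'   subject, drug, emotion, stimulus, trial_index, muscle, window,
#'   log_emg), `outliers` (an `outlier_report`), `spec`.
#' @export
preprocess_emg <- function(sim, spec = NULL, rule = "union") {
  fs <- sim$config$fs
  if (is.null(spec))
    spec <- if (fs / 2 > 400) filter_spec() else desk_filter_spec()
  trials <- sim$trials
  n <- nrow(trials)
  stats_rows <- vector("list", 2L * n)
  epochs <- vector("list", 2L * n)
  for (m in 1:2) {
    mus <- MUSCLE_LEVELS[m]
    for (i in seq_len(n)) {
      env <- filter_chain(sim$signals[[mus]][i, ], fs, spec)
      ep <- epoch_and_normalize(env, fs, sim$onset_sample,
                                epoch_pre = sim$config$epoch_pre,
                                epoch_post = sim$config$epoch_post)
      j <- (m - 1L) * n + i
      epochs[[j]] <- ep
      stats_rows[[j]] <- cbind(
        data.frame(subject = trials$subject_id[i], muscle = mus,
                   trial_index = trials$trial_index[i],
                   stringsAsFactors = FALSE),
        epoch_stats(ep))
    }
  }
  stats <- do.call(rbind, stats_rows)
  rep_out <- detect_outlier_trials(stats, rule = rule)
  keep <- which(!rep_out$flags$excluded)
  binned <- vector("list", length(keep))
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    i <- ((j - 1L) %% n) + 1L
    mus <- rep_out$flags$muscle[j]
    lw <- bin_log_windows(epochs[[j]])
    binned[[jj]] <- data.frame(subject = trials$subject_id[i],
                               drug = trials$drug[i],
                               emotion = trials$emotion[i],
                               stimulus = trials$stimulus_face_id[i],
                               trial_index = trials$trial_index[i],
                               muscle = mus, window = 1:5, log_emg = lw,
                               stringsAsFactors = FALSE)
  }
  binned <- do.call(rbind, binned)
  rownames(binned) <- NULL
  structure(list(binned = binned, outliers = rep_out, spec = spec),
            class = "emg_preprocessed")
}
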