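#' Simulate raw facial-EMG recordings for the full design
#'
#' Generates per-trial two-channel (ZM, CS) surface-EMG signals whose
#' post-stimulus amplitude envelope follows the asymptotic log
#' proportion-of-baseline trajectory implied by a [ground_truth()]:
#' for every trial the window-level mean trajectory
#' \eqn{\mu(w) = a_i - (a_i - b_i)\,e^{-e^{c_i}(w-1)}}, with subject
#' random effects on a, b, c, a per-face stimulus intercept, and
#' window-level residual noise, is interpolated piecewise-linearly
#' across the five window centres and applied as
#' `baseline_rms * exp(mu(t))` amplitude modulation of band-limited
#' Gaussian noise (passband inside the analysis bandpass). Amplitude
#' modulation — rather than additive tones — means rectification and
#' smoothing recover `exp(mu)` up to a common rectified-noise constant
#' that cancels in baseline normalisation. A 50 Hz line-interference
#' sinusoid is added; the pre-stimulus envelope is flat at
#' `baseline_rms`; a fraction `outlier_rate` of trials has its whole
#' amplitude multiplied by `outlier_factor`.
#'
#' @param config a [design_config()].
#' @param truth a [ground_truth()].
#' @param seed integer seed; identical (config, truth, seed) give
#'   bit-identical output.
#' @return list of class `emg_simulation`: `trials` (metadata incl. the
#'   injected `outlier` flag), `signals` (list ZM/CS of trials x samples
#'   microvolt matrices), `onset_sample`, `time`, `truth_windows`
#'   (noise-free window trajectories `mu` for recovery tests),
#'   `config`, `truth`.
#' @export
simulate_emg <- function(config, truth, seed = config$seed) {
  stopifnot(inherits(config, "design_config"), inherits(truth, "ground_truth"))
  if (any(!is.finite(unlist(truth[!vapply(truth, is.character, TRUE)]))))
    stop("non-finite ground truth")
  restore <- local_rng(seed)
  on.exit(restore())

  subs <- subject_frame(config)
  n_sub <- nrow(subs)
  fs <- config$fs
  n_pre <- round(config$epoch_pre * fs)
  n_post <- round(config$epoch_post * fs)
  n_samp <- n_pre + n_post + 1L
  onset <- n_pre + 1L
  tt <- (seq_len(n_samp) - onset) / fs

  # subject random effects (non-centred truth: independent across cells)
  u_a <- matrix(rnorm(n_sub * 4, 0, rep(truth$sd_subject_a, each = n_sub)), n_sub, 4)
  u_b <- matrix(rnorm(n_sub * 4, 0, rep(truth$sd_subject_b, each = n_sub)), n_sub, 4)
  u_c <- matrix(rnorm(n_sub * 4, 0, rep(truth$sd_subject_c, each = n_sub)), n_sub, 4)
  stim_int <- rnorm(config$n_faces, 0, truth$sd_stimulus)

  cells <- truth_cells(truth)
  noise_high <- min(380, 0.4 * fs)
  bp <- signal::butter(4, c(20, noise_high) / (fs / 2), type = "pass")
  centers <- (1:5) - 0.5     # window centres in s post-onset
  line_ph <- runif(n_sub * config$n_trials, 0, 2 * pi)

  trials_list <- vector("list", n_sub)
  sig <- list(ZM = matrix(0, n_sub * config$n_trials, n_samp),
              CS = matrix(0, n_sub * config$n_trials, n_samp))
  tw <- vector("list", n_sub)
  post_idx <- which(tt >= 0)

  for (s in seq_len(n_sub)) {
    seqd <- make_trial_sequence(config, seed = seed + 7919L * s)
    seqd$subject_id <- subs$subject_id[s]
    seqd$drug <- subs$drug[s]
    seqd$outlier <- runif(config$n_trials) < truth$outlier_rate
    trials_list[[s]] <- seqd
    d <- match(subs$drug[s], DRUG_LEVELS)
    tw_s <- vector("list", config$n_trials)
    for (i in seq_len(config$n_trials)) {
      row <- (s - 1L) * config$n_trials + i
      amp_fac <- if (seqd$outlier[i]) truth$outlier_factor else 1
      mus <- matrix(NA_real_, 5, 2)
      for (m in 1:2) {
        k <- match(paste(MUSCLE_LEVELS[m], seqd$emotion[i], sep = "."),
                   cell4_labels())
        a_i <- truth$a_cell[k] + truth$drug_delta_a[d] + u_a[s, k]
        b_i <- truth$b_fixed + u_b[s, k]
        c_i <- truth$c_cell[k] + truth$drug_delta_c[d] + u_c[s, k]
        mu_w <- asymptotic_curve(a_i, b_i, c_i, 1:5) +
          stim_int[seqd$stimulus_face_id[i]]
        mus[, m] <- mu_w
        eps <- rnorm(5, 0, truth$sigma_resid)
        # window-mean trajectory interpolated linearly; the residual is
        # piecewise-constant per window so binned means recover mu + eps
        w_of_t <- pmin(pmax(floor(tt[post_idx]) + 1L, 1L), 5L)
        mu_t <- stats::approx(centers, mu_w, xout = tt[post_idx],
                              rule = 2)$y + eps[w_of_t]
        amp <- rep(truth$baseline_rms, n_samp)
        # outlier trials are post-onset artefacts: scaling the whole
        # trial would cancel in baseline normalisation
        amp[post_idx] <- amp_fac * truth$baseline_rms * exp(mu_t)
        carrier <- signal::filtfilt(bp, rnorm(n_samp))
        carrier <- carrier / stats::sd(carrier)
        x <- amp * carrier +
          truth$line_noise_amp * sin(2 * pi * 50 * tt + line_ph[row])
        sig[[MUSCLE_LEVELS[m]]][row, ] <- x
      }
      tw_s[[i]] <- data.frame(subject_id = subs$subject_id[s],
                              trial_index = i,
                              muscle = rep(MUSCLE_LEVELS, each = 5),
                              window = rep(1:5, 2),
                              mu = c(mus[, 1], mus[, 2]))
    }
    tw[[s]] <- do.call(rbind, tw_s)
  }
  trials <- do.call(rbind, trials_list)
  rownames(trials) <- NULL
  structure(list(trials = trials, signals = sig, onset_sample = onset,
                 time = tt, truth_windows = do.call(rbind, tw),
                 config = config, truth = truth),
            class = "emg_simulation")
}

#' Simulate analysis-ready binned log-EMG rows directly
#'
#' Fast path for calibration and power simulations: draws the same
#' window-level model as [simulate_emg()] (cell trajectory + subject and
#' stimulus random effects + residual) but emits `BinnedEMGRow`-shaped
#' data without synthesising and re-filtering raw signals. No outlier
#' trials are injected.
#'
#' @inheritParams simulate_emg
#' @return data.frame with columns subject, drug, emotion, stimulus,
#'   muscle, window, log_emg, mu_true.
#' @export
simulate_binned <- function(config, truth, seed = config$seed) {
  stopifnot(inherits(config, "design_config"), inherits(truth, "ground_truth"))
  restore <- local_rng(seed)
  on.exit(restore())
  subs <- subject_frame(config)
  n_sub <- nrow(subs)
  u_a <- matrix(rnorm(n_sub * 4, 0, rep(truth$sd_subject_a, each = n_sub)), n_sub, 4)
  u_b <- matrix(rnorm(n_sub * 4, 0, rep(truth$sd_subject_b, each = n_sub)), n_sub, 4)
  u_c <- matrix(rnorm(n_sub * 4, 0, rep(truth$sd_subject_c, each = n_sub)), n_sub, 4)
  stim_int <- rnorm(config$n_faces, 0, truth$sd_stimulus)

  out <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    seqd <- make_trial_sequence(config, seed = seed + 7919L * s)
    d <- match(subs$drug[s], DRUG_LEVELS)
    k_per_m <- vapply(MUSCLE_LEVELS, function(m)
      match(paste(m, seqd$emotion, sep = "."), cell4_labels()),
      integer(config$n_trials))
    rows <- expand.grid(window = 1:5, muscle = MUSCLE_LEVELS,
                        trial_index = seq_len(config$n_trials),
                        stringsAsFactors = FALSE)
    k <- k_per_m[cbind(rows$trial_index, match(rows$muscle, MUSCLE_LEVELS))]
    a_i <- truth$a_cell[k] + truth$drug_delta_a[d] + u_a[s, k]
    b_i <- truth$b_fixed + u_b[s, k]
    c_i <- truth$c_cell[k] + truth$drug_delta_c[d] + u_c[s, k]
    mu <- asymptotic_curve(a_i, b_i, c_i, rows$window) +
      stim_int[seqd$stimulus_face_id[rows$trial_index]]
    out[[s]] <- data.frame(subject = subs$subject_id[s],
                           drug = subs$drug[s],
                           emotion = seqd$emotion[rows$trial_index],
                           stimulus = seqd$stimulus_face_id[rows$trial_index],
                           trial_index = rows$trial_index,
                           muscle = rows$muscle,
                           window = rows$window,
                           log_emg = mu + rnorm(nrow(rows), 0, truth$sigma_resid),
                           mu_true = mu,
                           stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

#' Simulate change-detection response times
#'
#' Correct-press RTs are log-normal around the 2.5 s morph midpoint with
#' a subject-level shift, truncated to (0, 5]; per-trial press status is
#' drawn with small configurable rates of missed, wrong-button, and
#' multiple presses. `group_shift` adds seconds per drug arm (default
#' zero, the study's null).
#'
#' @param config a [design_config()].
#' @param seed integer seed.
#' @param group_shift length-3 numeric, seconds added per drug arm.
#' @param sdlog within-subject log-scale SD.
#' @param sd_subject between-subject log-scale SD.
#' @param rate_none,rate_wrong,rate_multiple press-error rates.
#' @return data.frame: subject_id, drug, trial_index, emotion,
#'   stimulus_face_id, rt (NA unless correct), press_status.
#' @export
simulate_rts <- function(config, seed = config$seed,
                         group_shift = c(0, 0, 0),
                         sdlog = 0.25, sd_subject = 0.12,
                         rate_none = 0.02, rate_wrong = 0.01,
                         rate_multiple = 0.01) {
  stopifnot(rate_none + rate_wrong + rate_multiple < 1)
  group_shift <- rep_len(group_shift, 3)
  restore <- local_rng(seed)
  on.exit(restore())
  subs <- subject_frame(config)
  out <- vector("list", nrow(subs))
  for (s in seq_len(nrow(subs))) {
    seqd <- make_trial_sequence(config, seed = seed + 104729L * s)
    d <- match(subs$drug[s], DRUG_LEVELS)
    u <- rnorm(1, 0, sd_subject)
    status <- sample(c("correct", "none", "wrong_button", "multiple"),
                     config$n_trials, replace = TRUE,
                     prob = c(1 - rate_none - rate_wrong - rate_multiple,
                              rate_none, rate_wrong, rate_multiple))
    rt <- rep(NA_real_, config$n_trials)
    for (i in which(status == "correct")) {
      repeat {
        r <- 2.5 * exp(rnorm(1, u, sdlog)) + group_shift[d]
        if (r > 0 && r <= 5) break
      }
      rt[i] <- r
    }
    out[[s]] <- data.frame(subject_id = subs$subject_id[s],
                           drug = subs$drug[s],
                           trial_index = seqd$trial_index,
                           emotion = seqd$emotion,
                           stimulus_face_id = seqd$stimulus_face_id,
                           rt = rt, press_status = status,
                           stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

#' Simulate a demographic subject table
#'
#' Per-subject demographics shaped like the study's group-comparison
#' table: sex, age, BMI, hours from pill intake to task, and the
#' condition guess (most participants guess placebo, which makes guesses
#' in the placebo arm disproportionately correct).
#'
#' @param config a [design_config()].
#' @param seed integer seed.
#' @param p_female probability of female sex.
#' @param p_guess_placebo probability a subject guesses the placebo arm.
#' @return data.frame: subject_id, drug, sex, age, bmi, hours_from_pill,
#'   guessed_condition, correct_guess.
#' @export
simulate_subject_table <- function(config, seed = config$seed,
                                   p_female = 87 / 130,
                                   p_guess_placebo = 0.5) {
  restore <- local_rng(seed)
  on.exit(restore())
  subs <- subject_frame(config)
  n <- nrow(subs)
  age <- round(pmin(pmax(rnorm(n, 23.2, 3.55), 18), 35))
  bmi <- round(pmin(pmax(rnorm(n, 22.6, 2.49), 17), 30), 1)
  guess <- ifelse(runif(n) < p_guess_placebo, "placebo",
                  sample(c("amisulpride", "naltrexone"), n, replace = TRUE))
  data.frame(subs,
             sex = sample(c("F", "M"), n, replace = TRUE,
                          prob = c(p_female, 1 - p_female)),
             age = age, bmi = bmi,
             hours_from_pill = round(rnorm(n, 4.2, 0.25), 1),
             guessed_condition = guess,
             correct_guess = guess == subs$drug,
             stringsAsFactors = FALSE)
}

#' Persist a simulation to disk
#'
#' Trial metadata and ground truth go to CSV/JSON; the signal arrays to a
#' raw little-endian float64 container with a JSON sidecar recording
#' dimensions, sampling rate, onset sample, and channel names.
#'
#' @param sim an `emg_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(sim$truth), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "signals.f64"), "wb")
  for (m in MUSCLE_LEVELS) writeBin(as.vector(t(sim$signals[[m]])), con,
                                    size = 8, endian = "little")
  close(con)
  jsonlite::write_json(list(fs = sim$config$fs,
                            onset_sample = sim$onset_sample,
                            n_trials = nrow(sim$trials),
                            n_samples = ncol(sim$signals$ZM),
                            channels = MUSCLE_LEVELS,
                            layout = "channel-major, row-per-trial"),
                       file.path(dir, "signals.json"), auto_unbox = TRUE)
  invisible(dir)
}
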