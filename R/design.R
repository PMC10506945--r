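#' Study design configuration
#'
#' Describes the trial structure and acquisition parameters of a
#' facial-mimicry EMG session: three between-subject drug arms, dynamic
#' 5-s face stimuli (24 morph videos built from 10 face identities, each
#' repeated four times), two blocks, and raw EMG sampled from two muscles
#' (zygomaticus major, ZM; corrugator supercilii, CS).
#'
#' @param n_subjects_per_group subjects per drug arm (amisulpride,
#'   naltrexone, placebo).
#' @param n_trials trials per subject; must be a multiple of both
#'   `n_videos` and `blocks`.
#' @param n_faces number of face identities behind the videos.
#' @param n_videos number of distinct morph videos; half change
#'   HappyToAngry, half AngryToHappy.
#' @param blocks number of equal blocks the trial sequence is split into.
#' @param fs EMG sampling rate in Hz.
#' @param epoch_pre,epoch_post epoch extent in seconds before/after
#'   stimulus onset.
#' @param seed default seed recorded in the config (individual simulators
#'   take an explicit seed argument that overrides it).
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_subjects_per_group = 43,
                          n_trials = 96,
                          n_faces = 10,
                          n_videos = 24,
                          blocks = 2,
                          fs = 1200,
                          epoch_pre = 0.5,
                          epoch_post = 5,
                          seed = 1L) {
  stopifnot(n_subjects_per_group >= 1, n_trials >= 2, n_videos >= 2,
            blocks >= 1, fs > 0, epoch_pre > 0, epoch_post > 0)
  if (n_trials %% blocks != 0)
    stop("n_trials must be divisible by blocks")
  if (n_trials %% n_videos != 0)
    stop("n_trials must be a multiple of n_videos (whole repetitions)")
  if (n_videos %% 2 != 0)
    stop("n_videos must be even (two morph directions)")
  cfg <- list(n_subjects_per_group = as.integer(n_subjects_per_group),
              n_trials = as.integer(n_trials),
              n_faces = as.integer(n_faces),
              n_videos = as.integer(n_videos),
              blocks = as.integer(blocks),
              fs = fs,
              epoch_pre = epoch_pre,
              epoch_post = epoch_post,
              seed = as.integer(seed))
  class(cfg) <- "design_config"
  cfg
}

#' Desk-scale design profile
#'
#' A reduced design (12 subjects per group, 24 trials, 600 Hz sampling)
#' with the same statistical structure as the full study, sized so that a
#' complete simulate-to-model-comparison run finishes on one CPU at a
#' desk. At 600 Hz the Nyquist limit forces the analysis bandpass (and
#' the generator's noise passband) below the full-scale 400 Hz edge; see
#' [desk_filter_spec()].
#'
#' @param ... overrides passed to [design_config()].
#' @return A `design_config`.
#' @export
desk_config <- function(...) {
  args <- list(n_subjects_per_group = 12, n_trials = 24, fs = 600)
  args[names(list(...))] <- list(...)
  do.call(design_config, args)
}

DRUG_LEVELS    <- c("amisulpride", "naltrexone", "placebo")
MUSCLE_LEVELS  <- c("ZM", "CS")
EMOTION_LEVELS <- c("HappyToAngry", "AngryToHappy")

# subject-cell (muscle x emotion) labels, fixed order used throughout
cell4_labels <- function() {
  as.vector(outer(MUSCLE_LEVELS, EMOTION_LEVELS,
                  function(m, e) paste(m, e, sep = ".")))
}

#' Generating ground truth for the synthetic EMG study
#'
#' Holds the generative counterparts of the asymptotic-regression
#' parameters: per muscle-by-emotion cell asymptotes `a` and log-rates
#' `c` of the within-trial log proportion-of-baseline trajectory
#' (starting value `b` fixed at 0), subject and stimulus random-effect
#' SDs, residual SD on the log scale, and the raw-signal nuisance
#' structure (tonic baseline RMS, 50 Hz line interference, outlier
#' trials). Drug effects are additive shifts `drug_delta_a` /
#' `drug_delta_c` per arm and default to zero, so by default the three
#' arms are generated from an identical distribution (the study's null).
#'
#' Default effect sizes give clear mimicry: ZM activates toward happiness
#' (positive asymptote for AngryToHappy, negative for HappyToAngry) and
#' CS mirrors it for anger, with magnitudes of roughly 0.1 log units —
#' the order of magnitude of the asymptote prior scale.
#'
#' @param a_cell length-4 named numeric: asymptote per muscle x emotion
#'   cell, order ZM.HappyToAngry, CS.HappyToAngry, ZM.AngryToHappy,
#'   CS.AngryToHappy (see [cell4_labels()] — stored names win).
#' @param c_cell length-4 numeric, log rate per cell.
#' @param sd_subject_a,sd_subject_b,sd_subject_c subject random-effect
#'   SDs (recycled over the 4 cells).
#' @param sd_stimulus SD of the per-face intercept added to the log
#'   trajectory.
#' @param sigma_resid residual SD of window-level log proportion of
#'   baseline.
#' @param baseline_rms tonic pre-stimulus EMG RMS in microvolt.
#' @param line_noise_amp amplitude (microvolt) of the 50 Hz interference.
#' @param outlier_rate fraction of trials with inflated amplitude.
#' @param outlier_factor amplitude multiplier for outlier trials.
#' @param drug_delta_a,drug_delta_c length-3 additive drug shifts
#'   (amisulpride, naltrexone, placebo), default zero.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(a_cell = c(ZM.HappyToAngry = -0.10,
                                    CS.HappyToAngry = 0.08,
                                    ZM.AngryToHappy = 0.10,
                                    CS.AngryToHappy = -0.10),
                         c_cell = c(-0.5, -0.5, -0.5, -0.5),
                         sd_subject_a = 0.05,
                         sd_subject_b = 0.03,
                         sd_subject_c = 0.10,
                         sd_stimulus = 0.02,
                         sigma_resid = 0.20,
                         baseline_rms = 8,
                         line_noise_amp = 1,
                         outlier_rate = 0.02,
                         outlier_factor = 8,
                         drug_delta_a = c(0, 0, 0),
                         drug_delta_c = c(0, 0, 0)) {
  lb <- cell4_labels()
  a_cell <- rep_len(a_cell, 4); c_cell <- rep_len(c_cell, 4)
  if (!is.null(names(a_cell)) && all(lb %in% names(a_cell)))
    a_cell <- a_cell[lb]
  names(a_cell) <- names(c_cell) <- lb
  tr <- list(a_cell = a_cell, c_cell = c_cell, b_fixed = 0,
             sd_subject_a = rep_len(sd_subject_a, 4),
             sd_subject_b = rep_len(sd_subject_b, 4),
             sd_subject_c = rep_len(sd_subject_c, 4),
             sd_stimulus = sd_stimulus,
             sigma_resid = sigma_resid,
             baseline_rms = baseline_rms,
             line_noise_amp = line_noise_amp,
             outlier_rate = outlier_rate,
             outlier_factor = outlier_factor,
             drug_delta_a = rep_len(drug_delta_a, 3),
             drug_delta_c = rep_len(drug_delta_c, 3))
  vals <- unlist(tr)
  if (any(!is.finite(vals))) stop("ground truth values must be finite")
  if (any(c(tr$sd_subject_a, tr$sd_subject_b, tr$sd_subject_c,
            tr$sd_stimulus, tr$sigma_resid) < 0))
    stop("SDs must be non-negative")
  if (tr$outlier_rate < 0 || tr$outlier_rate >= 1)
    stop("outlier_rate must lie in [0, 1)")
  class(tr) <- "ground_truth"
  tr
}

#' Per-cell generating parameters including drug shifts
#'
#' Expands a [ground_truth()] into the 12 drug x muscle x emotion cells
#' of the Bayesian model's fixed-effect design.
#'
#' @param truth a `ground_truth`.
#' @return data.frame with columns drug, muscle, emotion, a, c.
#' @export
truth_cells <- function(truth) {
  g <- expand.grid(muscle = MUSCLE_LEVELS, emotion = EMOTION_LEVELS,
                   drug = DRUG_LEVELS, stringsAsFactors = FALSE)
  k <- match(paste(g$muscle, g$emotion, sep = "."), cell4_labels())
  d <- match(g$drug, DRUG_LEVELS)
  data.frame(drug = g$drug, muscle = g$muscle, emotion = g$emotion,
             a = unname(truth$a_cell[k] + truth$drug_delta_a[d]),
             c = unname(truth$c_cell[k] + truth$drug_delta_c[d]))
}

subject_frame <- function(config) {
  n <- config$n_subjects_per_group
  data.frame(subject_id = sprintf("S%03d", seq_len(3 * n)),
             drug = rep(DRUG_LEVELS, each = n),
             stringsAsFactors = FALSE)
}
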