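#' Semi-random trial sequence with bounded emotion runs
#'
#' Builds one subject's stimulus order: every video appears exactly
#' `n_trials / n_videos` times, the sequence is split into `blocks` equal
#' blocks, and no more than three consecutive trials share the same
#' morph direction (emotion). Videos are assigned a face identity
#' (cycling over `n_faces`) and an emotion (odd videos HappyToAngry,
#' even videos AngryToHappy).
#'
#' The order is drawn by seeded greedy sampling: trials are picked one at
#' a time uniformly from the remaining stimuli that do not create a run
#' of four, restarting the block on a dead end. Balanced designs succeed
#' in a handful of attempts; structurally unsatisfiable requests (one
#' emotion outnumbering what runs of three can accommodate) error.
#'
#' @param config a [design_config()].
#' @param seed integer seed; same seed, same sequence.
#' @param max_run longest permitted same-emotion run (default 3).
#' @return data.frame with columns trial_index, block, stimulus_face_id,
#'   video_id, emotion.
#' @export
make_trial_sequence <- function(config, seed = config$seed, max_run = 3L) {
  reps <- config$n_trials / config$n_videos
  videos <- data.frame(
    video_id = seq_len(config$n_videos),
    stimulus_face_id = ((seq_len(config$n_videos) - 1L) %% config$n_faces) + 1L,
    emotion = rep(EMOTION_LEVELS, length.out = config$n_videos))
  per_block <- config$n_trials / config$blocks
  # deal each emotion's stimuli round-robin over blocks so every block
  # holds a near-even emotion mix (a one-emotion block cannot satisfy
  # the run constraint)
  pool_ids <- rep(videos$video_id, reps)
  pool_emo <- videos$emotion[match(pool_ids, videos$video_id)]
  blk <- integer(length(pool_ids))
  for (e in unique(pool_emo)) {
    i <- which(pool_emo == e)
    blk[i] <- rep(seq_len(config$blocks), length.out = length(i))
  }
  # equalise block sizes if the dealing left a remainder imbalance
  repeat {
    sz <- tabulate(blk, config$blocks)
    if (max(sz) - min(sz) <= 0) break
    from <- which.max(sz); to <- which.min(sz)
    blk[which(blk == from)[1]] <- to
  }
  pool_split <- split(pool_ids, blk)
  n_emo <- table(pool_emo)
  if (max(n_emo) > max_run * (min(n_emo) + 1))
    stop("emotion counts cannot satisfy the maximum-run constraint")

  rng <- local_rng(seed)
  draw_block <- function(ids, prev_tail) {
    emo <- videos$emotion[match(ids, videos$video_id)]
    for (attempt in 1:2000) {
      left <- ids; left_emo <- emo
      out <- integer(0)
      run_emo <- if (length(prev_tail)) prev_tail$emo else ""
      run_len <- if (length(prev_tail)) prev_tail$len else 0L
      ok <- TRUE
      while (length(left)) {
        cand <- if (run_len >= max_run) which(left_emo != run_emo)
                else seq_along(left)
        if (!length(cand)) { ok <- FALSE; break }
        j <- cand[sample.int(length(cand), 1L)]
        e <- left_emo[j]
        run_len <- if (identical(e, run_emo)) run_len + 1L else 1L
        run_emo <- e
        out <- c(out, left[j])
        left <- left[-j]; left_emo <- left_emo[-j]
      }
      if (ok) return(out)
    }
    stop("could not build a trial sequence under the run constraint")
  }

  seq_ids <- integer(0); tail_state <- list()
  for (b in seq_len(config$blocks)) {
    blk <- draw_block(pool_split[[b]], tail_state)
    # run constraint is enforced within and across block boundaries
    emo_all <- videos$emotion[match(c(seq_ids, blk), videos$video_id)]
    r <- rle(emo_all)
    tail_state <- list(emo = r$values[length(r$values)],
                       len = r$lengths[length(r$lengths)])
    seq_ids <- c(seq_ids, blk)
  }
  rng()  # restore RNG state

  i <- match(seq_ids, videos$video_id)
  data.frame(trial_index = seq_len(config$n_trials),
             block = rep(seq_len(config$blocks), each = per_block),
             stimulus_face_id = videos$stimulus_face_id[i],
             video_id = videos$video_id[i],
             emotion = videos$emotion[i],
             stringsAsFactors = FALSE)
}

# set the RNG to `seed`, return a function restoring the previous state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

max_emotion_run <- function(emotion) max(rle(as.character(emotion))$lengths)
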