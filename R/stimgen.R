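# Stimulus generation: dynamic 1-D noise fields, ramping target, spatial cue.
#
# Conventions: frames are 1-based; frame f spans [(f-1)*dt, f*dt) ms with
# dt = 1000/30 ms. Field 1 = left, field 2 = right. Event times in ms are
# measured from noise (stimulus) onset; cue onset is stored unquantized,
# with the containing frame derived from it.

frame_start_ms <- function(f, sp) (f - 1) * sp$frame_duration_ms

# frame containing time ms (frame f covers [(f-1)*dt, f*dt)); the epsilon
# keeps exact frame-boundary times in the frame that starts there
ms_to_frame <- function(ms, sp) {
  as.integer(floor(ms / sp$frame_duration_ms + 1e-9)) + 1L
}

# deterministic per-trial seed stream (kept below 2^31 - 1)
trial_seed <- function(session_seed, i) {
  as.integer((as.double(session_seed) %% 2147483647 * 48271 + i * 10007) %% 2147483647)
}

#' Target contrast ramp
#'
#' Contrast of the target signal `t` frames after the onset of target
#' addition: `10 ^ min(0.05 * t - 3, 0)`. The log10 contrast rises by 0.05
#' per frame from -3 and saturates at contrast 1 (at t = 60 frames).
#'
#' @param t integer frames since target onset (vectorized, must be >= 0).
#' @param params a [stim_params()] object (ramp slope and offset).
#' @return contrast values in (0, 1].
#' @export
#' @examples
#' target_contrast(0)   # 0.001
#' target_contrast(60)  # 1
target_contrast <- function(t, params = stim_params()) {
  if (any(t < 0)) stop("t must be >= 0 (frames since target onset)")
  10^pmin(params$target_ramp_slope * t + params$target_ramp_offset, 0)
}

#' Generate a noise-only stimulus movie
#'
#' Two independent fields of `n_bars_per_field` bars whose contrasts are
#' redrawn each frame i.i.d. from Normal(0, `noise_sd`). The pre-clipping
#' Gaussian samples are stored in `$noise`; `$contrast` holds the clipped
#' display contrast.
#'
#' @param params a [stim_params()] object.
#' @param seed integer RNG seed; the movie is bit-reproducible given the seed.
#' @return A `stimulus_movie`: list with `noise` and `contrast` arrays of
#'   dimension (bar, frame, field), `params`, `seed`, and empty target/cue
#'   metadata.
#' @export
make_noise_movie <- function(params = stim_params(), seed = 1L) {
  set.seed(seed)
  nb <- params$n_bars_per_field
  nf <- params$n_frames
  noise <- array(stats::rnorm(nb * nf * 2, 0, params$noise_sd), c(nb, nf, 2),
                 dimnames = list(NULL, NULL, c("left", "right")))
  movie <- list(
    noise = noise,
    contrast = clip_contrast(noise, params),
    target_side = NULL, target_onset_frame = NULL, cue = NULL,
    params = params, seed = seed
  )
  class(movie) <- "stimulus_movie"
  movie
}

clip_contrast <- function(x, params) {
  pmin(pmax(x, params$clip_range[1]), params$clip_range[2])
}

#' Add the ramping target to a stimulus movie
#'
#' From `onset_frame` on, the contrast ramp of [target_contrast()] is added
#' linearly to the two central bars of the target field; the result is
#' clipped to `clip_range`. The pre-clipping noise samples in `$noise` are
#' left untouched (they are what the classification-image analysis uses).
#'
#' @param movie a `stimulus_movie`.
#' @param side `"left"` or `"right"`.
#' @param onset_frame 1-based frame at which target addition starts; its
#'   start time must lie within `target_onset_range_ms`.
#' @param params a [stim_params()] object.
#' @return The movie with updated `$contrast` and target metadata.
#' @export
add_target <- function(movie, side, onset_frame, params = movie$params) {
  side <- match.arg(side, c("left", "right"))
  onset_ms <- frame_start_ms(onset_frame, params)
  if (onset_ms < params$target_onset_range_ms[1] - 1e-6 ||
      onset_ms > params$target_onset_range_ms[2] + 1e-6)
    stop("target onset outside target_onset_range_ms")
  f_idx <- if (side == "left") 1L else 2L
  nf <- params$n_frames
  frames <- onset_frame:nf
  ramp <- target_contrast(frames - onset_frame, params)
  contrast <- clip_contrast(movie$noise, params)
  cb <- params$central_bars
  with_target <- movie$noise[cb, frames, f_idx] +
    rep(ramp, each = length(cb))
  contrast[cb, frames, f_idx] <- clip_contrast(with_target, params)
  movie$contrast <- contrast
  movie$target_side <- side
  movie$target_onset_frame <- as.integer(onset_frame)
  movie$target_onset_ms <- onset_ms
  movie
}

#' Schedule the spatial cue for one trial
#'
#' With probability `cue_probability` a 100-ms cue is scheduled; its side
#' equals the target side with probability `cue_validity` (valid cue) and is
#' the opposite side otherwise. Cue onset is drawn uniformly on
#' `cue_onset_range_ms` after target onset. Uses the current RNG state.
#'
#' @param target_side `"left"` or `"right"`.
#' @param target_onset_ms target onset time (ms from stimulus onset).
#' @param params a [stim_params()] object.
#' @return `NULL` (no cue) or a list with `side`, `onset_ms`, `offset_ms`,
#'   `onset_frame`, `valid`.
#' @export
schedule_cue <- function(target_side, target_onset_ms, params = stim_params()) {
  if (stats::runif(1) > params$cue_probability) return(NULL)
  valid <- stats::runif(1) < params$cue_validity
  side <- if (valid) target_side else setdiff(c("left", "right"), target_side)
  onset_ms <- target_onset_ms +
    stats::runif(1, params$cue_onset_range_ms[1], params$cue_onset_range_ms[2])
  list(side = side,
       onset_ms = onset_ms,
       offset_ms = onset_ms + params$cue_duration_ms,
       onset_frame = ms_to_frame(onset_ms, params),
       valid = valid)
}

# one trial's random structure: side, onset, cue, noise, accumulator noise.
# Draw order is fixed; everything downstream is deterministic given this.
gen_trial_core <- function(seed, params) {
  set.seed(seed)
  side <- if (stats::runif(1) < 0.5) "left" else "right"
  n_onsets <- ms_to_frame(params$target_onset_range_ms[2], params)
  onset_frame <- sample.int(n_onsets, 1L)
  onset_ms <- frame_start_ms(onset_frame, params)
  cue <- schedule_cue(side, onset_ms, params)
  nb <- params$n_bars_per_field
  nf <- params$n_frames
  noise <- array(stats::rnorm(nb * nf * 2, 0, params$noise_sd), c(nb, nf, 2),
                 dimnames = list(NULL, NULL, c("left", "right")))
  eps_std <- stats::rnorm(nf)
  list(seed = seed, target_side = side, target_onset_frame = onset_frame,
       target_onset_ms = onset_ms, cue = cue, noise = noise, eps_std = eps_std)
}

#' Generate a complete single-trial stimulus
#'
#' Draws target side, target onset, cue schedule, the noise movie, and the
#' trial's accumulator-noise stream from one seed, and assembles the clipped
#' contrast movie. The counterpart of [simulate_stimuli()] for one trial.
#'
#' @param params a [stim_params()] object.
#' @param seed integer RNG seed.
#' @return A `stimulus_movie` with target and cue metadata and an `eps_std`
#'   vector of standard-normal accumulator noise (scaled by the model's
#'   `noise_sd` at simulation time).
#' @export
make_trial_stimulus <- function(params = stim_params(), seed = 1L) {
  core <- gen_trial_core(seed, params)
  movie <- list(noise = core$noise, contrast = NULL,
                params = params, seed = seed)
  class(movie) <- "stimulus_movie"
  movie$contrast <- clip_contrast(core$noise, params)
  movie <- add_target(movie, core$target_side, core$target_onset_frame, params)
  movie$cue <- core$cue
  movie$eps_std <- core$eps_std
  movie
}

#' Generate the stimulus set for a session
#'
#' Per-trial seeds are derived deterministically from `seed`, so any single
#' trial can be regenerated in isolation with [make_trial_stimulus()] using
#' the stored per-trial seed.
#'
#' @param n_trials number of trials.
#' @param params a [stim_params()] object.
#' @param seed integer session seed.
#' @return An `rlci_stimuli` object: `meta` data frame (trial_id, seed,
#'   target side/onset, cue fields), `noise` array (bar, frame, field,
#'   trial) of pre-clipping Gaussian samples, `eps_std` matrix
#'   (trial, frame), and `params`.
#' @export
simulate_stimuli <- function(n_trials, params = stim_params(), seed = 1L) {
  stopifnot(n_trials >= 1)
  nb <- params$n_bars_per_field
  nf <- params$n_frames
  noise <- array(NA_real_, c(nb, nf, 2, n_trials))
  eps_std <- matrix(NA_real_, n_trials, nf)
  meta <- data.frame(
    trial_id = seq_len(n_trials),
    seed = NA_integer_,
    target_side = NA_character_,
    target_onset_frame = NA_integer_,
    target_onset_ms = NA_real_,
    cue_present = NA,
    cue_side = NA_character_,
    cue_onset_ms = NA_real_,
    cue_onset_frame = NA_integer_,
    cue_offset_ms = NA_real_,
    cue_valid = NA
  )
  for (i in seq_len(n_trials)) {
    core <- gen_trial_core(trial_seed(seed, i), params)
    noise[, , , i] <- core$noise
    eps_std[i, ] <- core$eps_std
    meta$seed[i] <- core$seed
    meta$target_side[i] <- core$target_side
    meta$target_onset_frame[i] <- core$target_onset_frame
    meta$target_onset_ms[i] <- core$target_onset_ms
    meta$cue_present[i] <- !is.null(core$cue)
    if (!is.null(core$cue)) {
      meta$cue_side[i] <- core$cue$side
      meta$cue_onset_ms[i] <- core$cue$onset_ms
      meta$cue_onset_frame[i] <- core$cue$onset_frame
      meta$cue_offset_ms[i] <- core$cue$offset_ms
      meta$cue_valid[i] <- core$cue$valid
    }
  }
  structure(list(meta = meta, noise = noise, eps_std = eps_std,
                 params = params, seed = seed),
            class = "rlci_stimuli")
}

#' Vectorized trial schedule (no noise movies)
#'
#' Draws target side/onset and the cue schedule for `n_trials` trials in one
#' RNG stream. Used for checking the design rates (cue probability, cue
#' validity, onset range) at large n without the cost of noise generation.
#'
#' @param n_trials number of trials.
#' @param params a [stim_params()] object.
#' @param seed integer seed.
#' @return Data frame with target_side, target_onset_ms, cue_present,
#'   cue_side, cue_valid, cue_onset_ms.
#' @export
schedule_trials <- function(n_trials, params = stim_params(), seed = 1L) {
  set.seed(seed)
  side <- ifelse(stats::runif(n_trials) < 0.5, "left", "right")
  n_onsets <- ms_to_frame(params$target_onset_range_ms[2], params)
  onset_ms <- frame_start_ms(sample.int(n_onsets, n_trials, replace = TRUE), params)
  cued <- stats::runif(n_trials) <= params$cue_probability
  valid <- stats::runif(n_trials) < params$cue_validity
  cue_side <- ifelse(valid, side, ifelse(side == "left", "right", "left"))
  cue_onset <- onset_ms + stats::runif(n_trials, params$cue_onset_range_ms[1],
                                       params$cue_onset_range_ms[2])
  data.frame(
    target_side = side, target_onset_ms = onset_ms, cue_present = cued,
    cue_side = ifelse(cued, cue_side, NA_character_),
    cue_valid = ifelse(cued, valid, NA),
    cue_onset_ms = ifelse(cued, cue_onset, NA_real_)
  )
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$noise)
  cat("Stimulus movie:", d[1], "bars x", d[2], "frames x 2 fields\n")
  if (!is.null(x$target_side))
    cat("  target:", x$target_side, "field, onset frame",
        x$target_onset_frame, "\n")
  if (!is.null(x$cue))
    cat(sprintf("  cue: %s field, onset %.1f ms (%s)\n", x$cue$side,
                x$cue$onset_ms, if (x$cue$valid) "valid" else "invalid"))
  else cat("  cue: none\n")
  invisible(x)
}
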