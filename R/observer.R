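# Model observer: spatiotemporal filtering with attentional gain, evidence
# comparison between fields, and noisy leaky accumulation to a boundary.

#' Attentional gain timeline
#'
#' Both fields have gain 1 until 50 ms (`attention_delay_ms`) after cue
#' onset; from the first frame starting at or after that moment to the end
#' of the trial, the cued field's gain is `params$gain` (sustained well past
#' cue offset) while the other field stays at 1. Without a cue, or with
#' gain 1, the timeline is all ones.
#'
#' @param cue cue metadata (list with `side`, `onset_ms`) or `NULL`.
#' @param params a [model_params()] object.
#' @param stim a [stim_params()] object (frame grid).
#' @return A 2 x n_frames matrix (rows left, right) with attribute
#'   `switch_ms`, the exact time `cue_onset_ms + attention_delay_ms` at
#'   which the gain change takes effect (NA without a cue).
#' @export
attention_gain_timeline <- function(cue, params, stim = stim_params()) {
  g <- matrix(1, 2, stim$n_frames, dimnames = list(c("left", "right"), NULL))
  switch_ms <- NA_real_
  if (!is.null(cue)) {
    switch_ms <- cue$onset_ms + params$attention_delay_ms
    # first frame whose start time (f-1)*dt is >= switch_ms
    f_on <- as.integer(ceiling(switch_ms / stim$frame_duration_ms - 1e-9)) + 1L
    if (f_on <= stim$n_frames) {
      row <- if (cue$side == "left") 1L else 2L
      g[row, f_on:stim$n_frames] <- params$gain
    }
  }
  attr(g, "switch_ms") <- switch_ms
  g
}

#' Perceptual response of the model front end
#'
#' Convolves each field's contrast movie with the separable spatiotemporal
#' filter (spatial difference-of-Gaussians at pixel resolution, causal
#' biphasic temporal kernel on the frame grid) and applies the per-frame
#' attentional gain. Linear in the stimulus and in the gain.
#'
#' @param movie a `stimulus_movie` (uses `$contrast`).
#' @param params a [model_params()] object.
#' @param gain_timeline optional 2 x n_frames gain matrix (defaults to the
#'   timeline implied by the movie's cue via [attention_gain_timeline()]).
#' @return Array (pixel, frame, field) of filter responses.
#' @export
perceptual_response <- function(movie, params, gain_timeline = NULL) {
  sp <- movie$params
  if (dim(movie$contrast)[1] != sp$n_bars_per_field ||
      dim(movie$contrast)[2] != sp$n_frames)
    stop("movie and stimulus parameter geometry disagree")
  if (is.null(gain_timeline))
    gain_timeline <- attention_gain_timeline(movie$cue, params, sp)
  M <- spatial_bar_matrix(params, sp)
  KT <- temporal_kernel_matrix(params, sp$n_frames)
  out <- array(0, c(sp$n_pixels, sp$n_frames, 2),
               dimnames = list(NULL, NULL, c("left", "right")))
  for (f in 1:2) {
    filtered <- M %*% (movie$contrast[, , f] %*% KT)
    out[, , f] <- filtered * rep(gain_timeline[f, ], each = sp$n_pixels)
  }
  out
}

#' Momentary sensory evidence
#'
#' Difference between the spatial sums of absolute filter responses:
#' `dR(t) = sum_x |R_left(x, t)| - sum_x |R_right(x, t)|`. Positive values
#' favor "target left".
#'
#' @param R_left,R_right pixel x frame response matrices of equal shape.
#' @return evidence vector over frames.
#' @export
evidence_signal <- function(R_left, R_right) {
  if (!identical(dim(R_left), dim(R_right)))
    stop("field responses must have equal shape")
  colSums(abs(R_left)) - colSums(abs(R_right))
}

#' Leaky accumulation to a decision boundary
#'
#' Cumulative evidence `S(T) = sum_{t=1}^{T} (gamma^(T-t) dR(t) + eps_t)`:
#' the momentary evidence decays with per-frame factor `gamma` while the
#' internal noise terms `eps_t ~ Normal(0, noise_sd)` accumulate without
#' leak (the formula's literal reading; see the `leak_noise` switch). The
#' first frame at which `S(T) >= bound` yields choice "left",
#' `S(T) <= -bound` choice "right"; no crossing by the last frame is a
#' lapse. Response time adds the constant motor delay.
#'
#' @param dR evidence vector over frames.
#' @param params a [model_params()] object.
#' @param eps_std optional standard-normal noise vector (length of `dR`),
#'   scaled by `params$noise_sd`; drawn from the current RNG if missing.
#' @param stim a [stim_params()] object (frame duration).
#' @param leak_noise if `TRUE`, the internal noise decays with `gamma`
#'   exactly like the evidence (the common alternative convention).
#' @return A `decision_outcome`: list with `choice` ("left"/"right"/"none"),
#'   `decision_frame`, `rt_ms` (`decision_frame * frame_duration +
#'   motor_delay_ms`, NA on lapse), `lapsed`, and the `evidence` trace S(T).
#' @export
accumulate_and_decide <- function(dR, params, eps_std = NULL,
                                  stim = stim_params(), leak_noise = FALSE) {
  nf <- length(dR)
  if (is.null(eps_std)) eps_std <- stats::rnorm(nf)
  eps <- eps_std * params$noise_sd
  x <- if (leak_noise) dR + eps else dR
  L <- as.numeric(stats::filter(x, params$gamma, method = "recursive"))
  S <- if (leak_noise) L else L + cumsum(eps)
  hit <- which(abs(S) >= params$bound)
  if (length(hit) == 0) {
    out <- list(choice = "none", decision_frame = NA_integer_, rt_ms = NA_real_,
                lapsed = TRUE, evidence = S)
  } else {
    Tdec <- hit[1]
    out <- list(choice = if (S[Tdec] > 0) "left" else "right",
                decision_frame = as.integer(Tdec),
                rt_ms = Tdec * stim$frame_duration_ms + params$motor_delay_ms,
                lapsed = FALSE, evidence = S)
  }
  class(out) <- "decision_outcome"
  out
}

#' Simulate one trial of the model observer
#'
#' Chains gain timeline, perceptual response, evidence signal, and
#' accumulation for a complete single-trial stimulus. Fully reproducible:
#' the outcome is a deterministic function of the movie (which carries its
#' seed and accumulator-noise stream) and the parameters.
#'
#' @param movie a `stimulus_movie` from [make_trial_stimulus()] (must carry
#'   target and cue metadata; `eps_std` is used as the accumulator noise).
#' @param params a [model_params()] object.
#' @param leak_noise see [accumulate_and_decide()].
#' @return One-row data frame: a trial record with choice, rt_ms, correct,
#'   lapsed, excluded plus the stimulus metadata columns.
#' @export
simulate_trial <- function(movie, params, leak_noise = FALSE) {
  if (is.null(movie$target_side)) stop("movie has no target; use add_target()")
  sp <- movie$params
  stimuli <- structure(list(
    meta = data.frame(
      trial_id = 1L, seed = movie$seed, target_side = movie$target_side,
      target_onset_frame = movie$target_onset_frame,
      target_onset_ms = frame_start_ms(movie$target_onset_frame, sp),
      cue_present = !is.null(movie$cue),
      cue_side = if (is.null(movie$cue)) NA_character_ else movie$cue$side,
      cue_onset_ms = if (is.null(movie$cue)) NA_real_ else movie$cue$onset_ms,
      cue_onset_frame = if (is.null(movie$cue)) NA_integer_ else movie$cue$onset_frame,
      cue_offset_ms = if (is.null(movie$cue)) NA_real_ else movie$cue$offset_ms,
      cue_valid = if (is.null(movie$cue)) NA else movie$cue$valid),
    noise = array(movie$noise, c(dim(movie$noise), 1)),
    eps_std = matrix(if (is.null(movie$eps_std)) stats::rnorm(sp$n_frames)
                     else movie$eps_std, 1),
    params = sp, seed = movie$seed), class = "rlci_stimuli")
  run_observer(stimuli, params, leak_noise = leak_noise)
}

#' Run the model observer over a stimulus set
#'
#' Applies the full model (target addition and clipping, spatiotemporal
#' filtering, attentional gain, evidence comparison, leaky accumulation) to
#' every trial of an [simulate_stimuli()] set. The heavy linear algebra is
#' batched over trials in fixed-size chunks; the result is deterministic
#' given the stimulus set and parameters (common random numbers: the
#' accumulator noise is the stimulus set's `eps_std` scaled by
#' `params$noise_sd`).
#'
#' @param stimuli an `rlci_stimuli` object.
#' @param params a [model_params()] object.
#' @param leak_noise see [accumulate_and_decide()].
#' @param chunk_size trials per linear-algebra batch.
#' @return Trial-record data frame: stimulus metadata plus `choice`,
#'   `decision_frame`, `rt_ms`, `response_frame` (frame containing rt_ms,
#'   capped at the movie length), `correct`, `lapsed`, and `excluded`
#'   (lapse, error, or rt past the deadline - the trials the analyses drop).
#' @export
run_observer <- function(stimuli, params, leak_noise = FALSE, chunk_size = 32L) {
  fs <- perceptual_field_sums(stimuli, params, chunk_size = chunk_size)
  decide_trials(fs, stimuli, params, leak_noise = leak_noise)
}

#' Perceptual stage: spatial sums of absolute filter responses
#'
#' The gain-independent front end of the model: adds the target ramp, clips,
#' convolves with the spatiotemporal filter, and returns
#' `sum_x |R(x, t)|` per field, frame, and trial (before any attentional
#' gain, which multiplies these sums since it is a positive per-field
#' scalar). Cache this when refitting only decision-stage parameters
#' (gain, gamma, bound, noise_sd).
#'
#' @param stimuli an `rlci_stimuli` object.
#' @param params a [model_params()] object (uses the filter parameters).
#' @param chunk_size trials per linear-algebra batch.
#' @return Array (field, trial, frame) of absolute-response sums.
#' @export
perceptual_field_sums <- function(stimuli, params, chunk_size = 32L) {
  sp <- stimuli$params
  meta <- stimuli$meta
  n <- nrow(meta)
  nb <- sp$n_bars_per_field
  nf <- sp$n_frames
  M <- spatial_bar_matrix(params, sp)
  KT <- temporal_kernel_matrix(params, nf)
  cb <- sp$central_bars
  out <- array(NA_real_, c(2, n, nf))
  for (start in seq(1, n, by = chunk_size)) {
    idx <- start:min(n, start + chunk_size - 1L)
    m <- length(idx)
    # (bar, field, trial, frame), ramp added, clipped
    X <- aperm(stimuli$noise[, , , idx, drop = FALSE], c(1, 3, 4, 2))
    for (j in seq_len(m)) {
      i <- idx[j]
      f_idx <- if (meta$target_side[i] == "left") 1L else 2L
      frames <- meta$target_onset_frame[i]:nf
      ramp <- target_contrast(frames - meta$target_onset_frame[i], sp)
      X[cb, f_idx, j, frames] <- X[cb, f_idx, j, frames] +
        rep(ramp, each = length(cb))
    }
    X <- clip_contrast(X, sp)
    dim(X) <- c(nb * 2 * m, nf)
    Xf <- X %*% KT                       # causal temporal filtering
    dim(Xf) <- c(nb, 2 * m * nf)
    R <- M %*% Xf                        # spatial filtering at pixel resolution
    fs <- colSums(abs(R))                # per-field spatial sum of |R|
    dim(fs) <- c(2, m, nf)
    out[, idx, ] <- fs
  }
  out
}

#' Decision stage: gain, evidence comparison, and leaky accumulation
#'
#' Applies the attentional gain timeline to cached perceptual field sums,
#' forms the left-minus-right evidence, accumulates it with decay `gamma`
#' plus internal noise, and finds the first boundary crossing per trial.
#'
#' @param fs array from [perceptual_field_sums()].
#' @param stimuli the matching `rlci_stimuli` (metadata and noise streams).
#' @param params a [model_params()] object.
#' @param leak_noise see [accumulate_and_decide()].
#' @return Trial-record data frame (see [run_observer()]).
#' @export
decide_trials <- function(fs, stimuli, params, leak_noise = FALSE) {
  sp <- stimuli$params
  meta <- stimuli$meta
  n <- nrow(meta)
  nf <- sp$n_frames
  gl <- matrix(1, n, nf)
  gr <- matrix(1, n, nf)
  if (params$gain != 1) {
    for (i in seq_len(n)) {
      if (isTRUE(meta$cue_present[i])) {
        sw <- meta$cue_onset_ms[i] + params$attention_delay_ms
        f_on <- as.integer(ceiling(sw / sp$frame_duration_ms - 1e-9)) + 1L
        if (f_on <= nf) {
          if (meta$cue_side[i] == "left") gl[i, f_on:nf] <- params$gain
          else gr[i, f_on:nf] <- params$gain
        }
      }
    }
  }
  dR <- gl * matrix(fs[1, , ], n, nf) - gr * matrix(fs[2, , ], n, nf)
  eps <- stimuli$eps_std * params$noise_sd
  x <- if (leak_noise) dR + eps else dR
  L <- t(stats::filter(t(x), params$gamma, method = "recursive"))
  S <- if (leak_noise) L else L + t(apply(eps, 1, cumsum))
  crossed <- abs(S) >= params$bound
  choice <- character(n); dec_frame <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hit <- which(crossed[i, ])
    if (length(hit)) {
      dec_frame[i] <- hit[1]
      choice[i] <- if (S[i, hit[1]] > 0) "left" else "right"
    } else choice[i] <- "none"
  }

  out <- meta
  out$choice <- choice
  out$decision_frame <- dec_frame
  out$lapsed <- is.na(dec_frame)
  out$rt_ms <- dec_frame * sp$frame_duration_ms + params$motor_delay_ms
  out$response_frame <- pmin(ms_to_frame(out$rt_ms, sp), nf)
  out$correct <- ifelse(out$lapsed, NA, out$choice == out$target_side)
  out$excluded <- out$lapsed | !out$correct | out$rt_ms > params$deadline_ms
  out$excluded[is.na(out$excluded)] <- TRUE
  out
}

#' Simulate a full behavioral session
#'
#' Generates `n_trials` stimuli (target side uniform left/right, onset and
#' cue randomized per the design) and runs the model observer on them.
#'
#' @param n_trials number of trials (a human session had 160; synthetic
#'   observers typically run 2000-3200).
#' @param stim a [stim_params()] object.
#' @param params a [model_params()] object.
#' @param seed integer session seed.
#' @param observer_id label stored in the trial records.
#' @param leak_noise see [accumulate_and_decide()].
#' @return An `rlci_session`: list with `trials` (trial records including
#'   `condition` from [assign_condition()]) and `stimuli`.
#' @export
simulate_session <- function(n_trials, stim = stim_params(),
                             params = model_params("valid"), seed = 1L,
                             observer_id = "model_obs", leak_noise = FALSE) {
  stimuli <- simulate_stimuli(n_trials, stim, seed)
  trials <- run_observer(stimuli, params, leak_noise = leak_noise)
  trials$observer_id <- observer_id
  trials$condition <- assign_condition(trials)
  structure(list(trials = trials, stimuli = stimuli, seed = seed,
                 model_params = params),
            class = "rlci_session")
}

#' @export
print.rlci_session <- function(x, ...) {
  tr <- x$trials
  cat("Model-observer session:", nrow(tr), "trials (seed", x$seed, ")\n")
  cat(sprintf("  correct %.1f%%, lapsed %.1f%%, excluded %.1f%%\n",
              100 * mean(tr$correct, na.rm = TRUE), 100 * mean(tr$lapsed),
              100 * mean(tr$excluded)))
  cat("  conditions:", paste(names(table(tr$condition)),
                             table(tr$condition), collapse = ", "), "\n")
  invisible(x)
}
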