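#' Stimulus parameters for the cued contrast-detection display
#'
#' Returns the parameter set describing the dynamic-noise display: two
#' one-dimensional noise fields of 16 vertical bars each, refreshed at 30 Hz
#' for 4500 ms with i.i.d. Gaussian contrast noise (SD 0.1); a target whose
#' log10 contrast ramps at 0.05 per frame from -3, added to the two central
#' bars of one field; and a 100-ms spatial cue flashed on 94% of trials,
#' valid on 75% of cued trials, 500-2000 ms after target onset.
#'
#' @param ... name-value overrides of the default fields.
#'
#' @return An object of class `stim_params`: a list with fields
#'   `n_bars_per_field`, `bar_width_deg`, `field_size_deg`, `frame_rate_hz`,
#'   `duration_ms`, `noise_sd`, `target_ramp_slope`, `target_ramp_offset`,
#'   `target_onset_range_ms`, `cue_probability`, `cue_validity`,
#'   `cue_onset_range_ms`, `cue_duration_ms`, `pixel_size_deg`, `clip_range`,
#'   plus derived geometry `n_frames`, `frame_duration_ms`, `n_pixels`,
#'   `bar_width_px`, `central_bars`, `adjacent_bars`.
#' @export
#' @examples
#' sp <- stim_params()
#' sp$n_frames      # 135 frames = 4500 ms at 30 Hz
#' sp$central_bars  # bars 8 and 9 carry the target
stim_params <- function(...) {
  p <- list(
    n_bars_per_field = 16L,
    bar_width_deg    = 0.29,
    field_size_deg   = 4.6,
    frame_rate_hz    = 30,
    duration_ms      = 4500,
    noise_sd         = 0.1,
    target_ramp_slope  = 0.05,
    target_ramp_offset = -3,
    target_onset_range_ms = c(0, 500),
    cue_probability  = 0.94,
    cue_validity     = 0.75,
    cue_onset_range_ms = c(500, 2000),
    cue_duration_ms  = 100,
    pixel_size_deg   = 0.018,
    clip_range       = c(-1, 1)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown stim_params field(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots

  p$frame_duration_ms <- 1000 / p$frame_rate_hz
  n_frames <- p$duration_ms / p$frame_duration_ms
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stop("duration_ms must be an integer number of frames")
  p$n_frames <- as.integer(round(n_frames))

  # pixel grid derived from the bar grid: 16 bars x 16 px = 256 px; the
  # nominal field size (4.6 deg at 0.018 deg/px) matches to within half a bar
  p$bar_width_px <- as.integer(round(p$bar_width_deg / p$pixel_size_deg))
  p$n_pixels <- p$n_bars_per_field * p$bar_width_px
  if (abs(p$n_pixels * p$pixel_size_deg - p$field_size_deg) >
      p$bar_width_deg / 2)
    stop("bar geometry inconsistent with the nominal field size")

  ctr <- p$n_bars_per_field / 2
  p$central_bars  <- as.integer(c(ctr, ctr + 1))
  p$adjacent_bars <- as.integer(c(ctr - 1, ctr + 2))

  stopifnot(p$noise_sd > 0,
            p$cue_probability >= 0, p$cue_probability <= 1,
            p$cue_validity >= 0, p$cue_validity <= 1)
  class(p) <- "stim_params"
  p
}

#' Model-observer parameters
#'
#' Parameters of the perceptual-decision model: a separable spatiotemporal
#' filter (difference-of-Gaussians in space, biphasic temporal impulse
#' response), an attentional gain applied to the cued field from 50 ms after
#' cue onset, and a noisy leaky accumulator of the left-right evidence
#' difference with decision boundary `bound` and a 250-ms motor delay.
#'
#' Two fitted profiles are shipped. `"valid"` is the valid-cue condition fit
#' (gain free, estimated at 1.20); `"invalid"` is the invalid-cue condition
#' fit (gain fixed at 1). The number of temporal-filter stages `n_stages` is
#' fixed at 5 in both.
#'
#' @param profile `"valid"` or `"invalid"`, selecting the shipped fitted
#'   parameter set; ignored fields can be overridden via `...`.
#' @param ... name-value overrides (e.g. `gain = 1.5`, `noise_sd = 0`).
#'
#' @return An object of class `model_params`: list with fields `sigma_c`,
#'   `sigma_s` (DoG SDs, pixels), `B` (negative-lobe amplitude ratio),
#'   `tau` (transient factor, frames), `n_stages`, `gamma` (per-frame
#'   evidence decay), `bound`, `noise_sd` (accumulator noise SD per frame,
#'   model units), `gain` (attentional gain A), `motor_delay_ms`,
#'   `attention_delay_ms`, `deadline_ms`.
#' @export
#' @examples
#' model_params("valid")$gain     # 1.20
#' model_params("invalid")$gain   # 1
model_params <- function(profile = c("valid", "invalid"), ...) {
  profile <- match.arg(profile)
  p <- switch(profile,
    valid = list(sigma_c = 2.94, sigma_s = 16.9, B = 0.505, tau = 2.38,
                 gamma = 0.207, bound = 356.0, noise_sd = 10.6, gain = 1.20),
    invalid = list(sigma_c = 2.92, sigma_s = 15.7, B = 0.490, tau = 2.41,
                   gamma = 0.212, bound = 353.5, noise_sd = 9.80, gain = 1)
  )
  p$n_stages <- 5L
  p$motor_delay_ms <- 250
  p$attention_delay_ms <- 50
  p$deadline_ms <- 4500
  p$profile <- profile
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown model_params field(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  validate_model_params(p)
  class(p) <- "model_params"
  p
}

validate_model_params <- function(p) {
  stopifnot(p$sigma_c > 0, p$sigma_s > 0, p$sigma_c < p$sigma_s,
            p$tau > 0, p$gamma >= 0, p$gamma < 1,
            p$bound > 0, p$noise_sd >= 0, p$gain > 0,
            p$n_stages >= 1, p$n_stages == round(p$n_stages))
  invisible(p)
}

#' Read a parameter profile from a YAML file
#'
#' Key/value profiles mirroring [stim_params()] or [model_params()] fields;
#' the defaults shipped under `inst/extdata/` are the study's display and the
#' two printed fitted parameter vectors.
#'
#' @param path path to a YAML file.
#' @param type `"stim"` or `"model"`.
#' @return A `stim_params` or `model_params` object.
#' @export
read_params <- function(path, type = c("stim", "model")) {
  type <- match.arg(type)
  y <- yaml::read_yaml(path)
  if (type == "stim") do.call(stim_params, y)
  else do.call(model_params, y)
}

#' @export
print.stim_params <- function(x, ...) {
  cat("Stimulus parameters:", x$n_bars_per_field, "bars/field,",
      x$n_frames, "frames @", x$frame_rate_hz, "Hz, noise SD", x$noise_sd, "\n")
  cat("  cue: P =", x$cue_probability, ", validity =", x$cue_validity,
      ", onset", x$cue_onset_range_ms[1], "-", x$cue_onset_range_ms[2],
      "ms after target\n")
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model-observer parameters (profile:", x$profile, ")\n")
  cat(sprintf("  sigma_c %.3g  sigma_s %.3g  B %.3g  tau %.3g  gamma %.3g\n",
              x$sigma_c, x$sigma_s, x$B, x$tau, x$gamma))
  cat(sprintf("  bound %.4g  noise_sd %.3g  gain %.3g  (n = %d stages)\n",
              x$bound, x$noise_sd, x$gain, x$n_stages))
  invisible(x)
}
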