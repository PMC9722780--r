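# Response-locked classification images and impact curves.

#' Response-locked classification image
#'
#' Reverse correlation of the stimulus noise with the response, locked
#' backward from the response frame: the weight at (bar, lag) is the mean
#' over trials of the pre-clipping noise sample at
#' `response_frame - lag` in the selected field. Left-target trials are
#' mirrored (field swapped, bar order reversed) so that all trials share
#' the right-target orientation; the two central bars stay bars 8 and 9.
#' Only correct, non-excluded trials contribute by default (response- and
#' target-sorting then coincide). Cells to which no trial contributes
#' (lags reaching before the movie started) are NA, not 0.
#'
#' @param trials trial records (needs `response_frame`, `target_side`,
#'   `choice`, `correct`, `excluded`).
#' @param stimuli the matching `rlci_stimuli` object.
#' @param field `"target"` or `"non_target"`: which noise field to analyze.
#' @param max_lag largest backward lag in frames (lag 0 = response frame).
#' @param use `"correct"` (default) restricts to correct non-excluded
#'   trials; `"all"` uses every non-lapsed trial.
#' @param estimator `"mean_noise"` (default; weights in contrast units) or
#'   `"pearson"` (per-cell Pearson correlation between the mirrored noise
#'   and the choice coded +1/-1 relative to the canonical target side,
#'   computed over all non-lapsed trials). With zero-mean i.i.d. noise and
#'   near-ceiling accuracy the two differ essentially by a constant scale.
#' @return An `rlci_ci`: list with `weights` (bar x lag matrix, lag 0..max_lag),
#'   `n_trials` per lag, `field`, `estimator`, `lag_ms`.
#' @export
response_locked_ci <- function(trials, stimuli, field = c("target", "non_target"),
                               max_lag = 45L, use = c("correct", "all"),
                               estimator = c("mean_noise", "pearson")) {
  field <- match.arg(field)
  use <- match.arg(use)
  estimator <- match.arg(estimator)
  sp <- stimuli$params
  nb <- sp$n_bars_per_field
  keep <- if (estimator == "pearson" || use == "all") !trials$lapsed
          else !trials$excluded & trials$correct
  keep[is.na(keep)] <- FALSE
  tr <- trials[keep, ]
  if (nrow(tr) == 0) stop("no usable trials for the classification image")

  sums <- matrix(0, nb, max_lag + 1L)
  sq <- matrix(0, nb, max_lag + 1L)
  xy <- matrix(0, nb, max_lag + 1L)
  n <- integer(max_lag + 1L)
  ysum <- numeric(max_lag + 1L); ysq <- numeric(max_lag + 1L)
  for (k in seq_len(nrow(tr))) {
    i <- tr$trial_id[k]
    rf <- tr$response_frame[k]
    lags <- 0:min(max_lag, rf - 1L)
    left_target <- tr$target_side[k] == "left"
    f_idx <- if (field == "target") (if (left_target) 1L else 2L)
             else (if (left_target) 2L else 1L)
    noise <- stimuli$noise[, rf - lags, f_idx, i, drop = FALSE]
    dim(noise) <- c(nb, length(lags))
    if (left_target) noise <- noise[nb:1, , drop = FALSE]
    cols <- lags + 1L
    sums[, cols] <- sums[, cols] + noise
    n[cols] <- n[cols] + 1L
    if (estimator == "pearson") {
      y <- if (tr$choice[k] == tr$target_side[k]) 1 else -1
      sq[, cols] <- sq[, cols] + noise^2
      xy[, cols] <- xy[, cols] + y * noise
      ysum[cols] <- ysum[cols] + y
      ysq[cols] <- ysq[cols] + 1
    }
  }
  nmat <- matrix(n, nb, max_lag + 1L, byrow = TRUE)
  if (estimator == "mean_noise") {
    w <- sums / nmat
    w[nmat == 0] <- NA_real_
  } else {
    ybar <- matrix(ysum / n, nb, max_lag + 1L, byrow = TRUE)
    xbar <- sums / nmat
    cov_xy <- xy / nmat - xbar * ybar
    vx <- sq / nmat - xbar^2
    vy <- matrix(ysq / n, nb, max_lag + 1L, byrow = TRUE) - ybar^2
    w <- cov_xy / sqrt(vx * vy)
    w[nmat == 0 | !is.finite(w)] <- NA_real_
  }
  structure(list(weights = w, n_trials = n, field = field,
                 estimator = estimator,
                 lag_ms = (0:max_lag) * sp$frame_duration_ms,
                 params = sp),
            class = "rlci_ci")
}

#' Center and surround impact curves
#'
#' Collapses a classification image over space into two traces versus time
#' before the response: `center` is the mean weight of the two central bars
#' (8 and 9, where the target ramps up) and `surround` the mean of the two
#' flanking bars (7 and 10).
#'
#' @param ci an `rlci_ci` from [response_locked_ci()].
#' @return An `impact_curves` data frame: lag_frame, lag_ms, center,
#'   surround, n_trials.
#' @export
impact_curves <- function(ci) {
  sp <- ci$params
  w <- ci$weights
  out <- data.frame(
    lag_frame = seq_len(ncol(w)) - 1L,
    lag_ms = ci$lag_ms,
    center = colMeans(w[sp$central_bars, , drop = FALSE]),
    surround = colMeans(w[sp$adjacent_bars, , drop = FALSE]),
    n_trials = ci$n_trials
  )
  class(out) <- c("impact_curves", "data.frame")
  out
}

#' Average impact curves across observers
#'
#' Equal-weight mean of per-observer curves on a common lag grid, with the
#' across-observer SEM (n - 1 denominator).
#'
#' @param curve_list list of `impact_curves` data frames.
#' @return Data frame with lag_frame, lag_ms, center, surround, center_sem,
#'   surround_sem, n_observers.
#' @export
aggregate_impact_curves <- function(curve_list) {
  stopifnot(length(curve_list) >= 1)
  lag <- curve_list[[1]]$lag_ms
  for (cv in curve_list)
    if (!isTRUE(all.equal(cv$lag_ms, lag))) stop("curves on different lag grids")
  ctr <- sapply(curve_list, `[[`, "center")
  srr <- sapply(curve_list, `[[`, "surround")
  k <- length(curve_list)
  out <- data.frame(
    lag_frame = curve_list[[1]]$lag_frame, lag_ms = lag,
    center = rowMeans(ctr), surround = rowMeans(srr),
    center_sem = if (k > 1) apply(ctr, 1, stats::sd) / sqrt(k) else NA_real_,
    surround_sem = if (k > 1) apply(srr, 1, stats::sd) / sqrt(k) else NA_real_,
    n_observers = k
  )
  class(out) <- c("impact_curves", "data.frame")
  out
}

#' Classification images in sliding cue-onset epochs
#'
#' Splits cued trials by the time from the response back to cue onset
#' (`rt_ms - cue_onset_ms`) into 500-ms windows shifted by 250 ms --
#' [0,500), [250,750), [500,1000), [750,1250), [1000,1500) by default; a
#' trial enters every window containing its value -- and computes a
#' classification image per window.
#'
#' @param trials,stimuli as in [response_locked_ci()].
#' @param window_ms window width.
#' @param step_ms shift between consecutive windows.
#' @param range_ms overall range covered by the windows.
#' @param ... passed to [response_locked_ci()].
#' @return List with one element per epoch: `epoch_start_ms`,
#'   `epoch_end_ms`, `n_trials`, `ci` (NULL when the window is empty).
#' @export
epoch_cis <- function(trials, stimuli, window_ms = 500, step_ms = 250,
                      range_ms = c(0, 1500), ...) {
  starts <- seq(range_ms[1], range_ms[2] - window_ms, by = step_ms)
  x <- trials$rt_ms - trials$cue_onset_ms
  lapply(starts, function(s) {
    inw <- !is.na(x) & trials$cue_present & x >= s & x < s + window_ms
    sub <- trials[inw, ]
    list(epoch_start_ms = s, epoch_end_ms = s + window_ms,
         n_trials = sum(!sub$excluded, na.rm = TRUE),
         ci = if (nrow(sub) && any(!sub$excluded & sub$correct, na.rm = TRUE))
           response_locked_ci(sub, stimuli, ...) else NULL)
  })
}

#' Peak impact
#'
#' Amplitude statistic of an impact curve: the arithmetic mean of the curve
#' samples whose lags lie within 300-400 ms (inclusive) before the response.
#'
#' @param curves an `impact_curves` data frame.
#' @param window_ms inclusive lag window in ms.
#' @return Named vector with `center` and `surround` peak impacts.
#' @export
peak_impact <- function(curves, window_ms = c(300, 400)) {
  inw <- curves$lag_ms >= window_ms[1] & curves$lag_ms <= window_ms[2]
  if (!any(inw)) stop("no curve samples inside the peak window")
  c(center = mean(curves$center[inw]), surround = mean(curves$surround[inw]))
}

#' @export
print.rlci_ci <- function(x, ...) {
  cat("Response-locked classification image (", x$field, " field, ",
      x$estimator, " estimator)\n", sep = "")
  cat("  ", nrow(x$weights), " bars x ", ncol(x$weights),
      " lags (0-", max(x$lag_ms), " ms); ", max(x$n_trials),
      " trials at lag 0\n", sep = "")
  invisible(x)
}
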