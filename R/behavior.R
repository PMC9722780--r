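# Reaction-time analysis: condition assignment, harmonic means, epoch tables.

#' Assign the cue condition of each trial
#'
#' Trials without a cue are `no_cue`, as are all trials in which the
#' response came at or before cue onset (the cue could not have influenced
#' the decision). Otherwise the trial is `valid` if the cue was on the
#' target side and `invalid` if on the opposite side. Lapsed trials get NA.
#'
#' @param trials trial-record data frame (needs `cue_present`, `cue_side`,
#'   `target_side`, `cue_onset_ms`, `rt_ms`, `lapsed`).
#' @return factor with levels valid, invalid, no_cue.
#' @export
assign_condition <- function(trials) {
  if (any(!trials$lapsed & is.na(trials$rt_ms)))
    stop("non-lapsed trial with missing rt_ms")
  lab <- ifelse(trials$lapsed, NA_character_,
         ifelse(!trials$cue_present | trials$rt_ms <= trials$cue_onset_ms,
                "no_cue",
         ifelse(trials$cue_side == trials$target_side, "valid", "invalid")))
  factor(lab, levels = c("valid", "invalid", "no_cue"))
}

#' Harmonic mean reaction time
#'
#' `n / sum(1 / rt)`; a central-tendency index less sensitive to the long
#' right tail of RT distributions than the arithmetic mean.
#'
#' @param rts positive reaction times (ms).
#' @return harmonic mean in ms; `NA` for an empty vector (missing, not 0).
#' @export
#' @examples
#' harmonic_mean_rt(c(200, 300))  # 240
harmonic_mean_rt <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) == 0) return(NA_real_)
  if (any(rts <= 0)) stop("reaction times must be positive")
  length(rts) / sum(1 / rts)
}

#' Reaction time by cue-onset epoch
#'
#' Bins trials into `epoch_ms`-wide epochs of cue onset time, measured
#' either from stimulus onset (`lock = "stimulus"`) or backward from the
#' response (`lock = "response"`, binning `rt_ms - cue_onset_ms`, so epoch
#' k collects trials whose cue came k to k+100 ms before the response).
#' Within each observer x condition x epoch cell the harmonic-mean RT is
#' taken first; the table then reports the across-observer mean and SEM
#' (n - 1 denominator).
#'
#' Excluded trials (lapses, errors, deadline overruns) are dropped, as are
#' trials without a cue (they have no cue onset to bin by).
#'
#' @param trials trial records with `observer_id` and `condition` columns.
#' @param lock `"stimulus"` or `"response"`.
#' @param epoch_ms epoch width in ms.
#' @param range_ms two-element range tiled by the epochs; defaults to
#'   [500, 2500) for stimulus lock and [0, 1500) for response lock.
#' @return Data frame: condition, epoch_start_ms, epoch_end_ms, mean_rt_ms,
#'   sem_ms, n_observers, n_trials. Empty cells are absent (missing), never
#'   reported as zero.
#' @export
rt_by_cue_onset <- function(trials, lock = c("stimulus", "response"),
                            epoch_ms = 100, range_ms = NULL) {
  lock <- match.arg(lock)
  if (is.null(trials$observer_id)) trials$observer_id <- "obs1"
  if (is.null(trials$condition)) trials$condition <- assign_condition(trials)
  keep <- !trials$excluded & trials$cue_present & !is.na(trials$condition)
  tr <- trials[keep, ]
  x <- switch(lock,
              stimulus = tr$cue_onset_ms,
              response = tr$rt_ms - tr$cue_onset_ms)
  if (is.null(range_ms))
    range_ms <- if (lock == "stimulus") c(500, 2500) else c(0, 1500)
  edges <- seq(range_ms[1], range_ms[2], by = epoch_ms)
  inb <- x >= range_ms[1] & x < range_ms[2]
  tr <- tr[inb, ]; x <- x[inb]
  bin <- findInterval(x, edges)

  cells <- stats::aggregate(
    list(hm_rt = tr$rt_ms),
    by = list(observer_id = tr$observer_id, condition = tr$condition, bin = bin),
    FUN = harmonic_mean_rt)
  counts <- stats::aggregate(
    list(n_trials = tr$rt_ms),
    by = list(condition = tr$condition, bin = bin), FUN = length)

  agg <- stats::aggregate(
    list(mean_rt_ms = cells$hm_rt),
    by = list(condition = cells$condition, bin = cells$bin), FUN = mean)
  sem <- stats::aggregate(
    list(sem_ms = cells$hm_rt),
    by = list(condition = cells$condition, bin = cells$bin),
    FUN = function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  nobs <- stats::aggregate(
    list(n_observers = cells$hm_rt),
    by = list(condition = cells$condition, bin = cells$bin), FUN = length)

  out <- Reduce(function(a, b) merge(a, b, by = c("condition", "bin")),
                list(agg, sem, nobs, counts))
  out$epoch_start_ms <- edges[out$bin]
  out$epoch_end_ms <- edges[out$bin] + epoch_ms
  out <- out[order(out$condition, out$epoch_start_ms),
             c("condition", "epoch_start_ms", "epoch_end_ms",
               "mean_rt_ms", "sem_ms", "n_observers", "n_trials")]
  rownames(out) <- NULL
  out
}
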