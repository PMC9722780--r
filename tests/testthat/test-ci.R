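# Build a stimulus set plus hand-assigned responses, bypassing the observer,
# so the CI estimator can be tested against known ground truth.
fake_trials <- function(st, response_frame, choice = NULL) {
  meta <- st$meta
  n <- nrow(meta)
  meta$response_frame <- rep_len(response_frame, n)
  meta$choice <- if (is.null(choice)) meta$target_side else rep_len(choice, n)
  meta$lapsed <- FALSE
  meta$rt_ms <- meta$response_frame * st$params$frame_duration_ms
  meta$correct <- meta$choice == meta$target_side
  meta$excluded <- !meta$correct
  meta
}

test_that("single-trial CI is that trial's mirrored response-locked noise", {
  sp <- stim_params()
  st <- simulate_stimuli(6, sp, seed = 55)
  tr <- fake_trials(st, response_frame = 100L)
  one <- tr[3, ]
  ci <- response_locked_ci(one, st, field = "target", max_lag = 20L)
  f_idx <- if (one$target_side == "left") 1L else 2L
  want <- st$noise[, 100 - (0:20), f_idx, 3]
  if (one$target_side == "left") want <- want[16:1, ]
  expect_equal(unname(ci$weights), unname(want))
  expect_equal(ci$n_trials, rep(1L, 21))
})

test_that("null responses give weights within 3 SE of zero", {
  sp <- stim_params()
  st <- fixture("null_stimuli", function() simulate_stimuli(3000, sp, seed = 606))
  set.seed(9)
  tr <- fake_trials(st, response_frame = sample(60:135, 3000, TRUE),
                    choice = sample(c("left", "right"), 3000, TRUE))
  tr$correct <- TRUE; tr$excluded <- FALSE  # keep all: responses are noise-blind
  ci <- response_locked_ci(tr, st, field = "target", max_lag = 40L)
  se <- sp$noise_sd / sqrt(matrix(ci$n_trials, 16, 41, byrow = TRUE))
  # simultaneous band over 656 cells plus chance-rate 3-SE exceedances
  expect_true(all(abs(ci$weights) <= 4.5 * se))
  expect_gt(mean(abs(ci$weights) <= 3 * se), 0.99)
  # null-CI scaling: max |weight| shrinks roughly as 1/sqrt(n)
  ci_small <- response_locked_ci(tr[1:300, ], st, field = "target", max_lag = 40L)
  expect_gt(max(abs(ci_small$weights)) / max(abs(ci$weights)), 1.5)
})

test_that("a planted decision rule is recovered at the planted bar and lag", {
  sp <- stim_params()
  st <- fixture("null_stimuli", function() simulate_stimuli(3000, sp, seed = 606))
  lag_star <- 8L
  rf <- 110L
  # choice = side whose bar-8 noise at the fixed backward lag is larger
  nl <- st$noise[8, rf - lag_star, 1, ]
  nr <- st$noise[8, rf - lag_star, 2, ]
  tr <- fake_trials(st, response_frame = rf,
                    choice = ifelse(nl > nr, "left", "right"))
  tr$correct <- TRUE; tr$excluded <- FALSE
  # analyze the chosen-side field: mirror by choice, not target
  tr$target_side <- tr$choice
  ci <- response_locked_ci(tr, st, field = "target", max_lag = 20L)
  peak <- which(ci$weights == max(ci$weights), arr.ind = TRUE)
  expect_equal(unname(peak[1, "row"]), 8)
  expect_equal(unname(peak[1, "col"]), lag_star + 1L)
})

test_that("impact curves collapse the CI onto center and surround bands", {
  sp <- stim_params()
  ci <- structure(list(weights = matrix(0.3, 16, 5), n_trials = rep(10L, 5),
                       field = "target", estimator = "mean_noise",
                       lag_ms = (0:4) * sp$frame_duration_ms, params = sp),
                  class = "rlci_ci")
  cv <- impact_curves(ci)
  expect_equal(cv$center, rep(0.3, 5))
  expect_equal(cv$surround, rep(0.3, 5))

  ci$weights[c(8, 9), ] <- 0.7
  ci$weights[c(7, 10), ] <- -0.7
  cv2 <- impact_curves(ci)
  expect_equal(cv2$center, rep(0.7, 5))
  expect_equal(cv2$surround, rep(-0.7, 5))

  # brute-force check on a random toy CI
  set.seed(4)
  ci$weights <- matrix(rnorm(16 * 5), 16, 5)
  cv3 <- impact_curves(ci)
  for (j in 1:5) {
    expect_equal(cv3$center[j], (ci$weights[8, j] + ci$weights[9, j]) / 2)
    expect_equal(cv3$surround[j], (ci$weights[7, j] + ci$weights[10, j]) / 2)
  }
})

test_that("epoch windows slide by 250 ms and assign trials by membership", {
  ses <- valid_session()
  eps <- epoch_cis(ses$trials, ses$stimuli)
  expect_length(eps, 5)
  expect_equal(sapply(eps, `[[`, "epoch_start_ms"), c(0, 250, 500, 750, 1000))
  expect_equal(sapply(eps, `[[`, "epoch_end_ms"), c(500, 750, 1000, 1250, 1500))
  # a trial at rt - cue_onset = 600 ms belongs to [250,750) and [500,1000) only
  tr600 <- ses$trials[!ses$trials$excluded, ][1, ]
  tr600$cue_onset_ms <- tr600$rt_ms - 600
  memb <- sapply(epoch_cis(tr600, ses$stimuli), function(e) e$n_trials == 1)
  expect_equal(memb, c(FALSE, TRUE, TRUE, FALSE, FALSE))

  # all values in one window: that epoch's CI equals the full-set CI
  tr1 <- ses$trials
  tr1$cue_onset_ms <- tr1$rt_ms - 300
  e1 <- epoch_cis(tr1, ses$stimuli)
  full <- response_locked_ci(tr1, ses$stimuli)
  expect_equal(e1[[1]]$ci$weights, full$weights)
  expect_null(e1[[4]]$ci)
})

test_that("peak impact averages the 300-400 ms window inclusively", {
  sp <- stim_params()
  cv <- data.frame(lag_frame = 0:15, lag_ms = (0:15) * sp$frame_duration_ms,
                   center = 0, surround = 0)
  cv$center[cv$lag_frame %in% 9:12] <- 1:4  # lags 300, 333.3, 366.7, 400 ms
  expect_equal(unname(peak_impact(cv)["center"]), mean(1:4))
  expect_equal(unname(peak_impact(cv)["surround"]), 0)
  cvc <- transform(cv, center = 0.42, surround = 0.42)
  expect_equal(unname(peak_impact(cvc)), c(0.42, 0.42))
  expect_error(peak_impact(cv[1:3, ]), "window")
})

test_that("left- and right-target subsets give consistent mirrored CIs", {
  ses <- valid_session()
  tr <- ses$trials
  ciL <- response_locked_ci(tr[tr$target_side == "left", ], ses$stimuli,
                            max_lag = 30L)
  ciR <- response_locked_ci(tr[tr$target_side == "right", ], ses$stimuli,
                            max_lag = 30L)
  pooled_se <- stim_params()$noise_sd *
    sqrt(1 / matrix(ciL$n_trials, 16, 31, byrow = TRUE) +
         1 / matrix(ciR$n_trials, 16, 31, byrow = TRUE))
  z <- (ciL$weights - ciR$weights) / pooled_se
  # statistically indistinguishable: no cell beyond 4.5 SE, <2% beyond 3 SE
  expect_true(all(abs(z) < 4.5))
  expect_lt(mean(abs(z) > 3), 0.02)
})
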