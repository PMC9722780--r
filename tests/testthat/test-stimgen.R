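test_that("target contrast ramp follows the log-linear law and saturates", {
  expect_equal(target_contrast(0), 1e-3)
  expect_equal(target_contrast(30), 10^(-1.5), tolerance = 1e-12)
  expect_equal(target_contrast(60), 1)
  expect_equal(target_contrast(100), 1)  # clamped exponent
  ramp <- target_contrast(0:100)
  expect_true(all(diff(ramp) >= 0))
  expect_error(target_contrast(-1), "frames since target onset")
})

test_that("display geometry resolves to the design constants", {
  sp <- stim_params()
  expect_identical(sp$n_frames, 135L)
  expect_identical(sp$n_pixels, 256L)
  expect_identical(sp$bar_width_px, 16L)
  expect_identical(sp$n_bars_per_field, 16L)
  expect_identical(sp$central_bars, c(8L, 9L))
  expect_identical(sp$adjacent_bars, c(7L, 10L))
  expect_equal(sp$frame_duration_ms, 1000 / 30)
})

test_that("noise movies are reproducible and fields independent", {
  sp <- stim_params()
  m1 <- make_noise_movie(sp, seed = 99)
  m2 <- make_noise_movie(sp, seed = 99)
  expect_identical(m1$noise, m2$noise)
  expect_false(identical(m1$noise, make_noise_movie(sp, seed = 100)$noise))

  # pooled sample SD within 1% of 0.1; field correlation near zero
  st <- fixture("noise_pool", function() simulate_stimuli(250, sp, seed = 7))
  left <- as.numeric(st$noise[, , 1, ])
  right <- as.numeric(st$noise[, , 2, ])
  n <- length(left) + length(right)
  expect_gte(n, 1e6)
  expect_equal(sd(c(left, right)), 0.1, tolerance = 0.01)
  expect_lt(abs(mean(c(left, right))), 3 * 0.1 / sqrt(n))
  expect_lt(abs(cor(left, right)), 0.01)
})

test_that("target addition affects only the central bars after onset", {
  sp <- stim_params()
  mv <- quiet_movie(onset_frame = 1L, side = "left")
  ramp <- target_contrast(0:(sp$n_frames - 1), sp)
  for (b in sp$central_bars)
    expect_equal(mv$contrast[b, , 1], pmin(ramp, 1))
  expect_true(all(mv$contrast[-sp$central_bars, , 1] == 0))
  expect_true(all(mv$contrast[, , 2] == 0))

  # clipping: noise 0.9 + target 0.5 is stored as 1.0
  mv2 <- make_noise_movie(sp, seed = 2)
  mv2$noise[8, 120, 2] <- 0.9   # ramp has saturated at 1.0 by frame 120
  mv2 <- add_target(mv2, "right", 10L, sp)
  expect_equal(unname(mv2$contrast[8, 120, 2]), 1.0)

  # difference contrast - noise reconstructs the ramp wherever unclipped
  mv3 <- make_noise_movie(sp, seed = 3)
  mv3 <- add_target(mv3, "right", 10L, sp)
  frames <- 10:135
  diffs <- mv3$contrast[9, frames, 2] - mv3$noise[9, frames, 2]
  expected <- target_contrast(frames - 10, sp)
  unclipped <- mv3$noise[9, frames, 2] + expected <= 1 &
    abs(mv3$noise[9, frames, 2]) <= 1
  expect_equal(diffs[unclipped], expected[unclipped], tolerance = 1e-12)
})

test_that("cue schedule reproduces the design rates and onset range", {
  sp <- stim_params()
  sch <- schedule_trials(1e5, sp, seed = 31)
  expect_equal(mean(sch$cue_present), 0.94, tolerance = 0.005 / 0.94)
  cued <- sch[sch$cue_present, ]
  expect_equal(mean(cued$cue_side == cued$target_side), 0.75,
               tolerance = 0.01 / 0.75)
  rel <- cued$cue_onset_ms - cued$target_onset_ms
  expect_true(all(rel >= 500 & rel <= 2000))
  # target onsets tile [0, 500] ms inclusive on the frame grid
  expect_setequal(unique(sch$target_onset_ms), (0:15) * (1000 / 30))
})

test_that("a session stimulus set regenerates trial-by-trial from seeds", {
  sp <- stim_params()
  st <- simulate_stimuli(5, sp, seed = 88)
  for (i in c(1L, 4L)) {
    mv <- make_trial_stimulus(sp, st$meta$seed[i])
    noise <- mv$noise
    dimnames(noise) <- NULL
    expect_identical(noise, st$noise[, , , i])
    expect_identical(mv$eps_std, st$eps_std[i, ])
    expect_identical(mv$target_side, st$meta$target_side[i])
    expect_identical(mv$target_onset_frame, st$meta$target_onset_frame[i])
    expect_identical(is.null(mv$cue), !st$meta$cue_present[i])
    if (!is.null(mv$cue)) expect_equal(mv$cue$onset_ms, st$meta$cue_onset_ms[i])
  }
})
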