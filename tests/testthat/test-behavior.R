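test_that("condition assignment follows the response-before-cue rule", {
  tr <- data.frame(
    cue_present = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    cue_side    = c(NA, "left", "right", "left", "left"),
    target_side = c("left", "left", "left", "left", "left"),
    cue_onset_ms = c(NA, 1200, 1200, 1200, 1200),
    rt_ms       = c(800, 900, 1500, 1500, 1200),
    lapsed      = FALSE
  )
  lab <- assign_condition(tr)
  expect_equal(as.character(lab),
               c("no_cue",   # cue never shown
                 "no_cue",   # responded before the cue (900 < 1200)
                 "invalid",  # cue opposite the target
                 "valid",
                 "no_cue"))  # rt exactly at cue onset: decided no later
  # relabeling is idempotent and labels partition the trials
  tr$condition <- lab
  expect_identical(assign_condition(tr), lab)
  expect_false(any(is.na(lab)))
  expect_error(assign_condition(data.frame(
    cue_present = TRUE, cue_side = "left", target_side = "left",
    cue_onset_ms = 1, rt_ms = NA_real_, lapsed = FALSE)), "missing rt")
})

test_that("harmonic mean RT has its closed-form values and bounds", {
  expect_equal(harmonic_mean_rt(c(200, 300)), 240)
  expect_equal(harmonic_mean_rt(c(100, 400)), 160)
  expect_equal(harmonic_mean_rt(rep(123, 7)), 123)
  expect_true(is.na(harmonic_mean_rt(numeric(0))))
  expect_error(harmonic_mean_rt(c(100, -5)), "positive")
  # harmonic <= arithmetic for any positive set
  set.seed(1)
  for (i in 1:20) {
    v <- rexp(sample(2:30, 1)) * 1000 + 1
    expect_lte(harmonic_mean_rt(v), mean(v))
  }
})

test_that("RT epoch tables reduce to harmonic means and report SEM", {
  # all trials of one observer in a single stimulus-locked bin
  tr <- data.frame(
    observer_id = "o1", cue_present = TRUE, cue_side = "left",
    target_side = "left", cue_onset_ms = c(510, 540, 580),
    rt_ms = c(2000, 2400, 3000), lapsed = FALSE, excluded = FALSE
  )
  tab <- rt_by_cue_onset(tr, lock = "stimulus")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$condition, factor("valid", c("valid", "invalid", "no_cue")))
  expect_equal(tab$mean_rt_ms, harmonic_mean_rt(c(2000, 2400, 3000)))
  expect_equal(tab$epoch_start_ms, 500)
  expect_equal(tab$n_trials, 3)

  # identical observers give zero SEM
  tr2 <- rbind(transform(tr, observer_id = "o1"),
               transform(tr, observer_id = "o2"))
  tab2 <- rt_by_cue_onset(tr2, lock = "stimulus")
  expect_equal(tab2$sem_ms, 0)
  expect_equal(tab2$n_observers, 2)
})

test_that("response-locked binning uses time from cue to response", {
  tr <- data.frame(
    observer_id = "o1", cue_present = TRUE, cue_side = "right",
    target_side = "right", cue_onset_ms = 1000,
    rt_ms = c(1250, 1620), lapsed = FALSE, excluded = FALSE
  )
  tab <- rt_by_cue_onset(tr, lock = "response")
  expect_equal(sort(tab$epoch_start_ms), c(200, 600))
  expect_equal(tab$n_trials, c(1, 1))
})
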