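test_that("a maximal surrogate trial has the designed trapezoid torque", {
  tr <- gen_emg_trial(torque_plateau = 100, seed = 5)
  expect_s3_class(tr, "emg_trial")
  expect_equal(nrow(tr$data), 5000)
  expect_gte(max(tr$data$torque), 95)
  expect_lte(max(tr$data$torque), 105)
  # ramps reach near zero at both ends
  expect_lt(abs(tr$data$torque[1]), 1)
  expect_lt(abs(tr$data$torque[5000]), 1)
})

test_that("a submaximal trial plateaus near the 40 % target", {
  tr <- gen_emg_trial(contraction = "submaximal", torque_plateau = 100,
                      target_fraction = 0.4, seed = 6)
  plateau <- tr$data$torque[2001:4000]
  expect_equal(mean(plateau), 40, tolerance = 2)
})

test_that("EMG amplitude is modulated by the torque envelope", {
  tr <- gen_emg_trial(seed = 8)
  rms <- function(v) sqrt(mean(v^2))
  plateau_rms <- rms(tr$data$emg_bf[2001:3000])
  early_rms <- rms(tr$data$emg_bf[1:150])  # ramp onset, envelope <= 0.3
  expect_gt(plateau_rms, early_rms)
  expect_gt(plateau_rms / early_rms, 3)
})

test_that("trial generation is deterministic per seed and validates its band", {
  a <- gen_emg_trial(seed = 10)
  b <- gen_emg_trial(seed = 10)
  expect_identical(a$data, b$data)
  expect_error(gen_emg_trial(emg_band = c(20, 600), sampling_rate = 1000),
               class = "emg_invalid_spec")
})

test_that("the default cohort is a complete balanced 16 x 2 x 3 x 2 design", {
  co <- gen_cohort(seed = 2)
  expect_length(co$trials, 192)
  counts <- dplyr::count(co$manifest, subject, condition, time, contraction)
  expect_true(all(counts$n == 1))
  expect_equal(nrow(counts), 16 * 2 * 3 * 2)
  # every trial carries consistent metadata
  m <- co$manifest[7, ]
  tr <- co$trials[[m$trial]]
  expect_identical(tr$meta$subject, m$subject)
  expect_identical(tr$meta$time_point, m$time)
})

test_that("cohort effect injection lands in the ground-truth table", {
  co <- gen_cohort(n_subjects = 2, seed = 3,
                   effect_map = list(sampen = c(WARM = 1, STRETCH = 1)))
  truth <- co$truth
  expect_equal(truth$shift[truth$time == "BASELINE"], 0)
  expect_equal(truth$shift[truth$time == "WARM"], 1)
})

test_that("simulated cohort tables are balanced and respond to injected shifts", {
  tab <- simulate_cohort_table(n_subjects = 16, seed = 4)
  counts <- dplyr::count(tab, subject, condition, time)
  expect_true(all(counts$n == 1))
  expect_equal(nrow(counts), 16 * 2 * 3)

  shifted <- simulate_cohort_table(
    n_subjects = 16, seed = 4, between_sd = 1, within_sd = 0.2,
    effect_map = list(y = c(WARM = 3, STRETCH = 3))
  )
  m <- tapply(shifted$value, shifted$time, mean)
  expect_gt(m[["WARM"]] - m[["BASELINE"]], 1)
})

test_that("null simulated cohorts give uniform time-effect p-values", {
  # coarse calibration: under the null, roughly 5 % of time effects
  # significant (full 500-replicate calibration lives in the acceptance suite)
  ps <- sapply(1:60, function(i) {
    tab <- simulate_cohort_table(n_subjects = 10, seed = 7000 + i)
    tidy(rm_anova_2way(tab))$p[2]
  })
  expect_lt(mean(ps < 0.05), 0.2) # nowhere near systematic rejection
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
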