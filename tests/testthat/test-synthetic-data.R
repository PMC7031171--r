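test_that("channel generation is bit-identical under a fixed seed", {
  sp <- channel_spec("L5_left", onset_mf = 95, normalized_slope = -0.25)
  x1 <- generate_semg_channel(sp, 10, 2000, seed = 123)
  x2 <- generate_semg_channel(sp, 10, 2000, seed = 123)
  expect_identical(x1, x2)
  x3 <- generate_semg_channel(sp, 10, 2000, seed = 124)
  expect_false(identical(as.numeric(x1), as.numeric(x3)))
  # generation must not disturb the global RNG stream
  set.seed(77); before <- rnorm(1)
  set.seed(77); invisible(generate_semg_channel(sp, 4, 2000, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("channel specs and trajectories are validated", {
  expect_error(channel_spec("L9_left"), "label")
  expect_error(channel_spec("L5_left", onset_mf = 10), "onset_mf")
  expect_error(channel_spec("L5_left", amplitude_rms = 0), "amplitude_rms")
  # trajectory dropping below the filter band is refused
  sp <- channel_spec("L5_left", onset_mf = 60, normalized_slope = -3)
  expect_error(generate_semg_channel(sp, 30, 2000, seed = 1),
               "filter band|trajectory")
  expect_error(generate_semg_channel(channel_spec("L5_left"), 2, 2000,
                                     seed = 1), "duration")
})

test_that("the spectral pipeline recovers programmed slopes and onsets", {
  # zero slope: stationary signal
  z <- vapply(1:20, function(s) recover_fit(100, 0, s)$slope_norm,
              numeric(1))
  expect_lt(abs(mean(z)), 0.02)
  # steep slope, recovered to within 0.05 %/s on the 20-seed mean
  f <- vapply(21:40, function(s) recover_fit(100, -0.5, s)$slope_norm,
              numeric(1))
  expect_lt(abs(mean(f) - (-0.5)), 0.05)
})

test_that("a multifidus-like cell recovers its programmed onset", {
  fits <- lapply(41:60, function(s) recover_fit(116.64, -0.19, s))
  onsets <- vapply(fits, function(f) f$intercept_hz, numeric(1))
  slopes <- vapply(fits, function(f) f$slope_norm, numeric(1))
  expect_lt(abs(mean(onsets) - 116.64), 3)
  expect_lt(abs(mean(slopes) - (-0.19)), 0.03)
})

test_that("generated recordings carry a consistent accelerometer trace", {
  rec <- generate_recording(default_specs(), angle = angle_profile(23, 0),
                            seed = 31)
  expect_s3_class(rec, "semg_recording")
  expect_equal(colnames(rec$semg), semg_labels())
  k <- trunk_angle(rec)
  expect_lt(abs(k$onset_angle - 23), 0.5)
  expect_lt(abs(k$drift_rate), 0.01)
})

test_that("recording generation validates the montage", {
  specs <- default_specs()
  expect_error(generate_recording(specs[1:5], seed = 1), "missing channel")
  dup <- specs; dup[[2]] <- dup[[1]]
  expect_error(generate_recording(dup, seed = 1), "duplicate|missing")
})

test_that("programmed asymmetry surfaces as compensated imbalance of the right sign", {
  rec <- generate_recording(default_specs(ratio = 1.2), seed = 32)
  a <- analyze_recording(rec)
  # oracle: the chosen transform applied to the programmed onset ratio
  expected <- symmetric_ratio(1.2)
  expect_gt(a$imbalance$compensated, 0)
  expect_lt(abs(a$imbalance$compensated - expected), 5)
  rec_sym <- generate_recording(default_specs(ratio = 1), seed = 32)
  a_sym <- analyze_recording(rec_sym)
  expect_lt(abs(a_sym$imbalance$compensated), 5)
})

test_that("cohorts with zero variance reproduce their cell means exactly", {
  mm <- matrix(c(-0.2, -0.1, -0.25, -0.15), 2, 2)
  spec <- cohort_spec(n_per_group = 3, group_means = mm,
                      variance_components = c(subject = 0, day = 0, side = 0,
                                              subject_day = 0,
                                              subject_side = 0,
                                              residual = 0),
                      n_days = 2)
  coh <- generate_cohort(spec, seed = 5)
  expect_equal(nrow(coh), 3 * 4 * 2 * 2)
  mu <- spec$group_means[cbind(coh$age_group, coh$sex)]
  expect_equal(coh$value, unname(mu))
})

test_that("cohort sample moments match the programmed structure", {
  vc <- c(subject = 4, day = 0, side = 0, subject_day = 0, subject_side = 0,
          residual = 1)
  spec <- cohort_spec(n_per_group = 150, group_means = 2,
                      variance_components = vc, n_days = 2)
  coh <- generate_cohort(spec, seed = 6)
  # grand mean within 3 SE (per-subject variance 4 + 1 across 600 subjects)
  se_mean <- sqrt((4 + 1 / 4) / 600)
  expect_lt(abs(mean(coh$value) - 2), 3 * se_mean)
  # single-observation variance = subject + residual
  subj_mean <- tapply(coh$value, coh$subject, mean)
  expect_lt(abs(var(subj_mean) - (4 + 1 / 4)), 3 * sqrt(2 / 599) * 4.25)
  expect_identical(coh, generate_cohort(spec, seed = 6))
})

test_that("cohort specs are validated", {
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(variance_components = c(subject = -1, day = 0,
                                                   side = 0, subject_day = 0,
                                                   subject_side = 0,
                                                   residual = 1)),
               ">= 0")
  expect_error(cohort_spec(group_means = matrix(0, 3, 2)), "2 x 2")
})
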