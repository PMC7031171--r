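test_that("a noiseless line is fitted exactly", {
  trel <- (0:53) / 2 + 0.375
  s <- make_series(100 - 0.5 * trel)
  f <- fatigue_fit(s)
  expect_equal(f$intercept_hz, 100, tolerance = 1e-10)
  expect_equal(f$slope_hz_s, -0.5, tolerance = 1e-10)
  expect_equal(f$slope_norm, -0.5, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_equal(f$n_points, 54)
  # constant series
  fc <- fatigue_fit(make_series(rep(90, 54)))
  expect_equal(fc$slope_hz_s, 0, tolerance = 1e-12)
  expect_equal(fc$slope_norm, 0, tolerance = 1e-12)
})

test_that("the normalized-slope identity and shift equivariance hold", {
  withr::with_seed(8, {
    for (i in 1:10) {
      mf <- 90 + rnorm(54, sd = 3) - 0.3 * ((0:53) / 2)
      f <- fatigue_fit(make_series(mf))
      expect_equal(f$slope_norm, 100 * f$slope_hz_s / f$intercept_hz,
                   tolerance = 1e-12)
      g <- fatigue_fit(make_series(mf + 25))
      expect_equal(g$intercept_hz, f$intercept_hz + 25, tolerance = 1e-8)
      expect_equal(g$slope_hz_s, f$slope_hz_s, tolerance = 1e-8)
    }
  })
})

test_that("excluded points are omitted, and too few points is an error", {
  excl <- rep(FALSE, 54); excl[c(5, 9, 20)] <- TRUE
  trel <- (0:53) / 2 + 0.375
  f <- fatigue_fit(make_series(100 - 0.5 * trel, excluded = excl))
  expect_equal(f$n_points, 51)
  expect_equal(f$slope_norm, -0.5, tolerance = 1e-10)  # line unchanged
  expect_error(fatigue_fit(make_series(c(100, 99, 98),
                                       excluded = c(FALSE, FALSE, TRUE))),
               "fewer than 4")
})

test_that("fatigue summary aggregates and breaks ties canonically", {
  mk <- function(lab, slope) {
    trel <- (0:53) / 2 + 0.375
    fatigue_fit(make_series(100 + slope * trel, electrode = lab))
  }
  slopes <- c(-0.1, -0.2, -0.3, -0.1, -0.2, -0.3)
  fits <- Map(mk, semg_labels(), slopes)
  s <- summarize_fatigue(unname(fits))
  expect_equal(s$all_mean$slope_norm, -0.2, tolerance = 1e-9)
  expect_equal(s$most_negative$electrode, "L2_left")
  expect_true(s$most_negative$slope_norm <=
                min(vapply(s$fits, function(f) f$slope_norm, numeric(1))) +
                1e-12)
  # equal slopes: aggregates coincide
  eq <- summarize_fatigue(unname(Map(mk, semg_labels(), rep(-0.2, 6))))
  expect_equal(eq$all_mean$slope_norm, -0.2, tolerance = 1e-9)
  expect_equal(eq$most_negative$slope_norm, -0.2, tolerance = 1e-9)
  expect_equal(eq$most_negative$electrode, "L5_left")  # first canonical
})

test_that("unusable electrodes are dropped from the aggregate with count", {
  mk <- function(lab, slope, usable = TRUE) {
    trel <- (0:53) / 2 + 0.375
    f <- fatigue_fit(make_series(100 + slope * trel, electrode = lab))
    f$usable <- usable
    f
  }
  fits <- Map(mk, semg_labels(), c(-0.1, -0.2, -0.3, -0.1, -0.2, -0.3))
  fits[["L2_left"]]$usable <- FALSE
  s <- summarize_fatigue(unname(fits))
  expect_equal(s$all_mean$n, 5)
  expect_equal(s$all_mean$slope_norm, mean(c(-0.1, -0.2, -0.1, -0.2, -0.3)),
               tolerance = 1e-9)
  expect_equal(s$most_negative$electrode, "L1_right")
  expect_error(summarize_fatigue(list(mk("L5_left", -0.1, usable = FALSE))),
               "no usable")
})

test_that("fatigue tables have one row per electrode plus aggregates", {
  rec <- generate_recording(default_specs(), seed = 33)
  a <- analyze_recording(rec)
  tab <- fatigue_table(a$fatigue, recording = "r1")
  expect_equal(nrow(tab), 8)
  expect_setequal(tab$electrode, c(semg_labels(), "all", "most_negative"))
})

test_that("slopes are tested against zero with the Bonferroni family", {
  z <- slope_vs_zero_test(rep(0, 10))
  expect_equal(z$t, 0)
  expect_false(z$significant)
  expect_equal(z$threshold, 0.0025)
  expect_error(slope_vs_zero_test(c(-0.1, -0.2)), "at least 3")
  expect_error(slope_vs_zero_test(rep(-0.2, 10)), "zero variance")
  # a clearly fatiguing subgroup is detected for every seed tried
  sig <- vapply(1:10, function(s) {
    slopes <- withr::with_seed(s, rnorm(50, -0.2, 0.05))
    slope_vs_zero_test(slopes)$significant
  }, logical(1))
  expect_true(all(sig))
})
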