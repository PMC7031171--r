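test_that("dependability follows the closed form", {
  vc <- c(subject = 9, day = 0.2, side = 0.2, subject_day = 0.3,
          subject_side = 0.1, residual = 0.2)  # error sum = 1
  rep1 <- dependability(vc)
  expect_equal(rep1$D, 0.9)
  expect_equal(rep1$sem_abs, 1)
  # no error variance at all
  perfect <- dependability(c(subject = 4, day = 0, side = 0,
                             subject_day = 0, subject_side = 0,
                             residual = 0))
  expect_equal(perfect$D, 1)
  expect_equal(perfect$sem_abs, 0)
  expect_error(dependability(c(subject = 0, day = 0, side = 0,
                               subject_day = 0, subject_side = 0,
                               residual = 0)), "undefined")
})

test_that("the absolute error variance is exactly the sum of its terms", {
  withr::with_seed(3, {
    for (i in 1:20) {
      vc <- setNames(runif(6, 0, 2),
                     c("subject", "day", "side", "subject_day",
                       "subject_side", "residual"))
      nd <- sample(1:4, 1); ns <- sample(1:2, 1)
      r <- dependability(vc, n_days = nd, n_sides = ns)
      manual <- vc[["day"]] / nd + vc[["side"]] / ns +
        vc[["subject_day"]] / nd + vc[["subject_side"]] / ns +
        vc[["residual"]] / (nd * ns)
      expect_equal(r$sem_abs^2, unname(manual), tolerance = 1e-12)
      expect_equal(r$D, unname(vc[["subject"]] / (vc[["subject"]] + manual)),
                   tolerance = 1e-12)
    }
  })
})

test_that("D grows with more days, more sides, and more subject variance", {
  vc <- c(subject = 2, day = 0.3, side = 0.2, subject_day = 0.4,
          subject_side = 0.3, residual = 0.5)
  d1 <- dependability(vc)$D
  expect_gt(dependability(vc, n_days = 3)$D, d1)
  expect_gt(dependability(vc, n_sides = 2)$D, d1)
  vc2 <- vc; vc2["subject"] <- 4
  expect_gt(dependability(vc2)$D, d1)
})

test_that("structured data yields the expected component pattern", {
  # subjects essentially constant across days and sides -> subject variance
  # dominates, all error facets collapse to the tiny measurement noise
  d <- expand.grid(subject = sprintf("S%02d", 1:40), day = 1:3,
                   side = c("left", "right"))
  d$value <- as.numeric(factor(d$subject)) * 0.5 +
    withr::with_seed(30, rnorm(nrow(d), sd = 0.01))
  vc <- variance_components(d)
  expect_gt(vc$sigma2[["subject"]], 0.5)
  other <- vc$sigma2[setdiff(names(vc$sigma2), "subject")]
  expect_true(all(other < 0.01))
})

test_that("REML recovers a residual-only structure", {
  spec <- cohort_spec(n_per_group = 50, group_means = 0,
                      variance_components = c(subject = 0, day = 0, side = 0,
                                              subject_day = 0,
                                              subject_side = 0,
                                              residual = 4),
                      n_days = 3)
  coh <- generate_cohort(spec, seed = 14)
  vc <- variance_components(coh)
  expect_lt(abs(vc$sigma2[["residual"]] - 4) / 4, 0.15)
  expect_lt(vc$sigma2[["subject"]], 0.6)
  expect_lt(vc$sigma2[["day"]], 0.6)
})

test_that("EMS and REML agree on a balanced design", {
  spec <- cohort_spec(n_per_group = 25, group_means = 0, n_days = 3)
  coh <- generate_cohort(spec, seed = 15)
  reml <- variance_components(coh)
  ems <- variance_components(coh, method = "ems")
  expect_equal(reml$sigma2, ems$sigma2, tolerance = 0.02)
  # EMS refuses unbalanced data
  expect_error(variance_components(coh[-1, ], method = "ems"), "balanced")
})

test_that("dependability estimated from generated cohorts matches closed form", {
  spec <- cohort_spec(n_per_group = 50, n_days = 3)  # default components
  truth <- dependability(spec$variance_components)$D
  ests <- vapply(1:5, function(i) {
    coh <- generate_cohort(spec, seed = 500 + i)
    dependability(variance_components(coh))$D
  }, numeric(1))
  expect_lt(abs(mean(ests) - truth), 0.05)
})

test_that("degenerate reliability designs are rejected", {
  d <- expand.grid(subject = sprintf("S%02d", 1:10), day = 1, side = "left")
  d$value <- rnorm(10)
  expect_error(variance_components(d), "single day and a single side")
  expect_error(variance_components(data.frame(subject = 1, day = 1,
                                              side = 1, value = 1)),
               "2 subjects")
})
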