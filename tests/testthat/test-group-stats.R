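test_that("Cohen's d matches its definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # means exactly one pooled SD apart
  a <- c(0, 1, 2); b <- a + 1
  expect_equal(cohens_d(b, a), 1)
  big <- withr::with_seed(20, list(a = rnorm(1e5), b = rnorm(1e5, 0.5)))
  expect_lt(abs(cohens_d(big$b, big$a) - 0.5), 0.01)
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("the mixed model recovers programmed group effects", {
  d_true <- 0.56
  spec0 <- cohort_spec()
  sd_single <- sqrt(spec0$variance_components[["subject"]] +
                      spec0$variance_components[["residual"]])
  mm <- matrix(0, 2, 2); mm[2, ] <- d_true * sd_single  # old slower
  ests <- vapply(1:8, function(i) {
    spec <- cohort_spec(n_per_group = 50, group_means = mm, n_days = 3)
    coh <- generate_cohort(spec, seed = 700 + i)
    agg <- aggregate(value ~ subject + age_group + sex + test_day,
                     data = coh, FUN = mean)
    gm <- fit_group_model(agg)
    # EMM difference young - old, on the metric scale
    -gm$cohens_d[["age_group"]] * gm$sd_between
  }, numeric(1))
  truth <- d_true * sd_single
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 3 * mc_se + 0.1 * truth)
})

test_that("identical groups give null estimates and no significance", {
  spec <- cohort_spec(n_per_group = 30, group_means = 0, n_days = 2)
  coh <- generate_cohort(spec, seed = 91)
  agg <- aggregate(value ~ subject + age_group + sex + test_day,
                   data = coh, FUN = mean)
  gm <- fit_group_model(agg)
  expect_s3_class(gm, "group_model")
  expect_true(all(c("age_group", "sex", "age_group x sex", "test_day") %in%
                    gm$fixed$term))
  expect_lt(abs(gm$cohens_d[["age_group"]]), 0.5)
  expect_true(all(gm$fixed$p_bonferroni >= gm$fixed$p))
  # Holm-adjusted EMM p-values are monotone in the raw p-values
  cc <- gm$contrasts[order(gm$contrasts$p), ]
  expect_true(all(diff(cc$p_holm) >= -1e-12))
  expect_true(all(cc$p_holm >= cc$p))
})

test_that("single-day designs fall back to a fixed-effects fit", {
  spec <- cohort_spec(n_per_group = 20, group_means = 0, n_days = 1)
  coh <- generate_cohort(spec, seed = 92)
  agg <- aggregate(value ~ subject + age_group + sex + test_day,
                   data = coh, FUN = mean)
  gm <- fit_group_model(agg)
  expect_false("test_day" %in% gm$fixed$term)
  expect_s3_class(gm$model, "lm")
})

test_that("group-model inputs are validated", {
  expect_error(fit_group_model(data.frame(subject = 1)), "missing column")
  d <- data.frame(subject = c("a", "b", "c"),
                  age_group = c("young", "young", "old"),
                  sex = "male", test_day = 1, value = 1:3)
  expect_error(fit_group_model(d), "2 subjects")
})

test_that("null effects yield power near alpha and no required n", {
  ps <- power_simulation(c(age_group = 0), alpha = 0.05,
                         n_grid = c(25), n_sims = 200, n_days = 2,
                         seed = 5)
  p_null <- ps$power$power[ps$power$comparison == "age_group"]
  expect_lt(abs(p_null - 0.05), 0.045)
  expect_true(is.na(ps$required_n))
})

test_that("the simulated requirement matches the two-sample closed form", {
  # one comparison, d = 0.5, alpha 0.01, power 0.9, single observation per
  # subject: the age contrast is a plain two-sample design with 2n per arm
  ps <- power_simulation(c(age_group = 0.5), alpha = 0.01,
                         target_power = 0.9, attrition_fraction = 0,
                         n_grid = seq(40, 90, by = 10), n_sims = 150,
                         sd_subject = 1, sd_residual = 0, n_days = 1,
                         seed = 6)
  analytic <- ceiling(power.t.test(delta = 0.5, sd = 1, sig.level = 0.01,
                                   power = 0.9)$n)  # per age group
  expect_false(is.na(ps$required_n))
  expect_lte(abs(2 * ps$required_n - analytic), 2 * 10)  # one grid step
})

test_that("stronger effects never need more subjects", {
  grid <- c(5, 10, 15, 20, 30, 40)
  weak <- power_simulation(c(age_group = 0.5), alpha = 0.05,
                           target_power = 0.8, n_grid = grid,
                           n_sims = 100, n_days = 2, seed = 7)
  strong <- power_simulation(c(age_group = 1.0), alpha = 0.05,
                             target_power = 0.8, n_grid = grid,
                             n_sims = 100, n_days = 2, seed = 7)
  expect_false(is.na(strong$required_n))
  weak_n <- if (is.na(weak$required_n)) max(grid) + 1 else weak$required_n
  expect_lte(strong$required_n, weak_n)
  # attrition inflates the recruitment figure
  expect_equal(strong$required_n_attrition,
               as.integer(ceiling(strong$required_n / 0.9)))
})
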