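#' Cohen's d for two independent groups
#'
#' Mean difference divided by the pooled standard deviation (variances
#' pooled with n - 1 weights). Conventional benchmarks: |d| > 0.2 small,
#' > 0.5 medium, > 0.8 large.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return Cohen's d (a minus b).
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation", call. = FALSE)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Mixed-effects age/sex group comparison for one fatigue outcome
#'
#' Fits the study's inferential model for one outcome across all test
#' days: fixed effects for age group, sex, their interaction and test day,
#' with a random intercept per person; Type III F tests use Satterthwaite
#' denominator degrees of freedom. The age/sex/interaction p-values are
#' Bonferroni-adjusted for the standard family of 5 outcome comparisons.
#' When age and sex effects are of interest post hoc, estimated marginal
#' mean (EMM) contrasts of age within sex and sex within age are computed
#' and Holm-adjusted. Cohen's d for each contrast is the EMM difference
#' divided by the model-implied between-subject SD
#' (\eqn{\sqrt{\sigma^2_{subject} + \sigma^2_{residual}}}).
#'
#' With a single test day the model reduces to ordinary least squares on
#' the same fixed effects (no random intercept is identifiable).
#'
#' @param data long `data.frame` with columns `subject`, `age_group`,
#'   `sex`, `test_day` and the outcome.
#' @param outcome name of the outcome column.
#' @param n_comparisons Bonferroni family size for the main comparisons.
#' @param emm compute EMM post hoc contrasts (requires both factors to
#'   vary).
#' @return Object of class `"group_model"`: `outcome`, `fixed` (term,
#'   F, df, p, p_bonferroni, significant at the 0.01-equivalent level),
#'   `contrasts` (EMM differences with Holm-adjusted p), `cohens_d`,
#'   `sd_between`, `model`, `singular`.
#' @export
fit_group_model <- function(data, outcome = "value", n_comparisons = 5,
                            emm = TRUE) {
  need <- c("subject", "age_group", "sex", "test_day", outcome)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- data.frame(subject = factor(data$subject),
                  age_group = factor(data$age_group,
                                     levels = intersect(
                                       c("young", "old"),
                                       unique(data$age_group))),
                  sex = factor(data$sex,
                               levels = intersect(c("male", "female"),
                                                  unique(data$sex))),
                  test_day = factor(data$test_day),
                  y = as.numeric(data[[outcome]]))
  d <- d[stats::complete.cases(d), ]
  cell_n <- table(d$age_group, d$sex)
  if (any(cell_n > 0 & cell_n < 2))
    stop("need at least 2 subjects per age x sex cell", call. = FALSE)
  vary_sex <- nlevels(droplevels(d$sex)) > 1
  vary_age <- nlevels(droplevels(d$age_group)) > 1
  if (!vary_age) stop("age_group does not vary", call. = FALSE)
  multi_day <- nlevels(droplevels(d$test_day)) > 1

  fe <- if (vary_sex) "age_group * sex" else "age_group"
  fe <- if (multi_day) paste(fe, "+ test_day") else fe

  singular <- FALSE
  if (multi_day) {
    form <- stats::as.formula(paste("y ~", fe, "+ (1 | subject)"))
    fit <- lmerTest::lmer(form, data = d,
                          control = lme4::lmerControl(
                            check.conv.singular = "ignore",
                            calc.derivs = FALSE))
    singular <- lme4::isSingular(fit)
    at <- stats::anova(fit, type = 3)
    fixed <- data.frame(term = rownames(at),
                        F = at[["F value"]],
                        df1 = at[["NumDF"]], df2 = at[["DenDF"]],
                        p = at[["Pr(>F)"]], stringsAsFactors = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sd_between <- sqrt(sum(vc$vcov))
  } else {
    form <- stats::as.formula(paste("y ~", fe))
    fit <- stats::lm(form, data = d)
    # with effects coding the sequential and partial tests agree for the
    # balanced two-factor layout; use drop-style F tests per term
    at <- stats::anova(fit)
    terms_keep <- setdiff(rownames(at), "Residuals")
    fixed <- data.frame(term = terms_keep,
                        F = at[terms_keep, "F value"],
                        df1 = at[terms_keep, "Df"],
                        df2 = at["Residuals", "Df"],
                        p = at[terms_keep, "Pr(>F)"],
                        stringsAsFactors = FALSE)
    sd_between <- summary(fit)$sigma
  }
  fixed$term <- sub(":", " x ", fixed$term)
  fixed$p_bonferroni <- pmin(1, fixed$p * n_comparisons)
  # family-wise 0.05, i.e. per-comparison 0.01 at the default family of 5
  fixed$significant <- fixed$p <= 0.05 / n_comparisons

  contrasts_df <- NULL
  d_values <- NULL
  if (emm && vary_sex && vary_age) {
    emm_age <- emmeans::emmeans(fit, ~ age_group | sex)
    emm_sex <- emmeans::emmeans(fit, ~ sex | age_group)
    c1 <- as.data.frame(emmeans::contrast(emm_age, "pairwise",
                                          adjust = "none"))
    c2 <- as.data.frame(emmeans::contrast(emm_sex, "pairwise",
                                          adjust = "none"))
    c1$comparison <- paste0(c1$contrast, " | sex=", c1$sex)
    c2$comparison <- paste0(c2$contrast, " | age=", c2$age_group)
    cc <- rbind(c1[c("comparison", "estimate", "SE", "p.value")],
                c2[c("comparison", "estimate", "SE", "p.value")])
    cc$p_holm <- stats::p.adjust(cc$p.value, "holm")
    cc$cohens_d <- cc$estimate / sd_between
    names(cc)[names(cc) == "p.value"] <- "p"
    contrasts_df <- cc
    # main-effect d: marginal EMM differences on the between-subject scale
    # (emmeans notes about averaging over the interaction are expected)
    m_age <- as.data.frame(emmeans::contrast(
      suppressMessages(emmeans::emmeans(fit, ~ age_group)),
      "pairwise", adjust = "none"))
    m_sex <- as.data.frame(emmeans::contrast(
      suppressMessages(emmeans::emmeans(fit, ~ sex)),
      "pairwise", adjust = "none"))
    d_values <- c(age_group = m_age$estimate[1] / sd_between,
                  sex = m_sex$estimate[1] / sd_between)
  } else if (emm && vary_age) {
    m_age <- as.data.frame(emmeans::contrast(
      suppressMessages(emmeans::emmeans(fit, ~ age_group)),
      "pairwise", adjust = "none"))
    d_values <- c(age_group = m_age$estimate[1] / sd_between)
  }

  structure(list(outcome = outcome,
                 fixed = fixed,
                 contrasts = contrasts_df,
                 cohens_d = d_values,
                 sd_between = sd_between,
                 adjustment = sprintf("bonferroni x %d (main), holm (EMM)",
                                      n_comparisons),
                 model = fit,
                 singular = singular),
            class = "group_model")
}

#' @export
print.group_model <- function(x, digits = 3, ...) {
  cat(sprintf("Group comparison for '%s' (%s)\n", x$outcome, x$adjustment))
  if (x$singular)
    cat("  note: singular random-effect fit; interpret with care\n")
  ft <- x$fixed
  for (i in seq_len(nrow(ft)))
    cat(sprintf("  %-18s F(%g, %.1f) = %6.2f  p = %-8.3g adj = %-8.3g%s\n",
                ft$term[i], ft$df1[i], ft$df2[i], ft$F[i], ft$p[i],
                ft$p_bonferroni[i], if (ft$significant[i]) " *" else ""))
  if (!is.null(x$cohens_d)) {
    cat("  Cohen's d:",
        paste(sprintf("%s = %.2f", names(x$cohens_d), x$cohens_d),
              collapse = ", "), "\n")
  }
  if (!is.null(x$contrasts)) {
    cat("  EMM contrasts (Holm-adjusted):\n")
    cc <- x$contrasts
    for (i in seq_len(nrow(cc)))
      cat(sprintf("    %-28s diff %+.3f (SE %.3f)  p_holm = %.3g\n",
                  cc$comparison[i], cc$estimate[i], cc$SE[i], cc$p_holm[i]))
  }
  invisible(x)
}

#' @export
summary.group_model <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' Monte Carlo power simulation for the mixed-model group comparison
#'
#' For each candidate per-cell sample size, simulates cohorts at the
#' study's analysis unit -- one bilateral-mean metric value per subject and
#' test day, with a persistent subject effect (`sd_subject`) and a
#' day-level error (`sd_residual`) -- applies programmed standardized
#' effect sizes to the age/sex cell means, fits [fit_group_model()], and
#' estimates the power of each requested comparison at significance level
#' `alpha` (the Bonferroni-corrected per-comparison level). Returns the
#' smallest grid size reaching `target_power` for all non-null
#' comparisons, inflated for an expected fraction of unusable recordings.
#'
#' Effect sizes are Cohen's d on the single-observation scale
#' \eqn{\sqrt{sd\_subject^2 + sd\_residual^2}}, so with `n_days = 1` the
#' age comparison reduces exactly to a two-sample t-test design and the
#' simulated requirement can be checked against [stats::power.t.test()].
#'
#' @param effects named numeric vector of standardized effect sizes for
#'   any of `age_group`, `sex`, `interaction`.
#' @param alpha per-comparison significance level.
#' @param target_power required power for every non-null comparison.
#' @param attrition_fraction expected fraction of lost recordings; the
#'   returned n is inflated by `1 / (1 - attrition_fraction)`.
#' @param n_grid increasing vector of per-cell sample sizes to scan.
#' @param n_sims simulated cohorts per grid point.
#' @param sd_subject,sd_residual between-subject and within-subject
#'   (day-to-day) SDs of the metric; defaults match the default
#'   [cohort_spec()] reliability structure.
#' @param n_days test days per subject.
#' @param seed integer seed.
#' @return Object of class `"power_sim"`: `power` (data.frame n x
#'   comparison x power), `required_n` (per cell, before attrition),
#'   `required_n_attrition`, `alpha`, `target_power`; `required_n` is `NA`
#'   when the target is not reached on the grid.
#' @export
power_simulation <- function(effects,
                             alpha = 0.01,
                             target_power = 0.9,
                             attrition_fraction = 0.1,
                             n_grid = c(25, 50, 75, 100),
                             n_sims = 100,
                             sd_subject = 0.153,
                             sd_residual = 0.044,
                             n_days = 3,
                             seed = 1) {
  if (!(alpha > 0 && alpha < 1) || !(target_power > 0 && target_power < 1))
    stop("alpha and target_power must lie in (0, 1)", call. = FALSE)
  if (is.unsorted(n_grid, strictly = TRUE))
    stop("n_grid must be strictly increasing", call. = FALSE)
  known <- c("age_group", "sex", "interaction")
  if (is.null(names(effects)) || length(setdiff(names(effects), known)))
    stop("effects must be named among: ", paste(known, collapse = ", "),
         call. = FALSE)
  sd_single <- sqrt(sd_subject^2 + sd_residual^2)
  d_age <- if ("age_group" %in% names(effects)) effects[["age_group"]] else 0
  d_sex <- if ("sex" %in% names(effects)) effects[["sex"]] else 0
  d_int <- if ("interaction" %in% names(effects)) effects[["interaction"]] else 0
  # cell means: marginal standardized differences equal the programmed d
  mm <- matrix(0, 2, 2, dimnames = list(c("young", "old"),
                                        c("male", "female")))
  mm["old", ] <- mm["old", ] + d_age * sd_single
  mm[, "male"] <- mm[, "male"] + d_sex * sd_single
  mm["old", "male"] <- mm["old", "male"] + d_int * sd_single

  seeds <- derive_seeds(seed, length(n_grid) * n_sims)
  si <- 0L
  term_map <- c(age_group = "age_group", sex = "sex",
                interaction = "age_group x sex")
  rows <- list()
  cells <- expand.grid(age_group = c("young", "old"),
                       sex = c("male", "female"),
                       stringsAsFactors = FALSE)
  for (n in n_grid) {
    hits <- stats::setNames(numeric(3), known)
    n_subj <- 4L * n
    frame <- data.frame(
      subject = rep(sprintf("S%04d", seq_len(n_subj)), each = n_days),
      age_group = rep(rep(cells$age_group, each = n), each = n_days),
      sex = rep(rep(cells$sex, each = n), each = n_days),
      test_day = rep(seq_len(n_days), n_subj),
      stringsAsFactors = FALSE)
    mu <- mm[cbind(frame$age_group, frame$sex)]
    for (s in seq_len(n_sims)) {
      si <- si + 1L
      frame$value <- withr::with_seed(seeds[si], {
        p <- stats::rnorm(n_subj, sd = sd_subject)
        mu + rep(p, each = n_days) +
          stats::rnorm(nrow(frame), sd = sd_residual)
      })
      gm <- fit_group_model(frame, "value", emm = FALSE)
      for (k in known) {
        row <- gm$fixed$term == term_map[[k]]
        if (any(row) && gm$fixed$p[row] <= alpha)
          hits[k] <- hits[k] + 1
      }
    }
    pw <- hits / n_sims
    rows[[length(rows) + 1L]] <- data.frame(
      n = n, comparison = known, power = unname(pw),
      stringsAsFactors = FALSE)
  }
  power <- do.call(rbind, rows)
  active <- names(effects)[effects != 0]
  required_n <- NA_integer_
  if (length(active)) {
    ok_n <- vapply(n_grid, function(n) {
      all(power$power[power$n == n & power$comparison %in% active] >=
            target_power)
    }, logical(1))
    if (any(ok_n)) required_n <- n_grid[which(ok_n)[1]]
  }
  structure(list(power = power,
                 required_n = required_n,
                 required_n_attrition = if (is.na(required_n)) NA_integer_
                 else as.integer(ceiling(required_n /
                                           (1 - attrition_fraction))),
                 alpha = alpha, target_power = target_power,
                 attrition_fraction = attrition_fraction,
                 effects = effects, n_sims = n_sims),
            class = "power_sim")
}

#' @export
print.power_sim <- function(x, ...) {
  cat(sprintf("Monte Carlo power simulation (alpha = %g, target = %g, %d sims/n)\n",
              x$alpha, x$target_power, x$n_sims))
  pw <- x$power[x$power$comparison %in% names(x$effects)[x$effects != 0], ]
  if (nrow(pw)) print(utils::head(pw, 20), row.names = FALSE)
  if (is.na(x$required_n)) {
    cat("  target power not reached on the grid\n")
  } else {
    cat(sprintf("  required n/cell: %d (%d allowing %.0f%% attrition)\n",
                x$required_n, x$required_n_attrition,
                100 * x$attrition_fraction))
  }
  invisible(x)
}
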