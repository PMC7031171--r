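#' Estimate variance components of the test-retest design
#'
#' Generalizability-theory decomposition of a fatigue metric observed over
#' crossed facets subject (the object of measurement), day and side:
#' \deqn{y = \mu + p + d + s + pd + ps + \epsilon}
#' Components are estimated by restricted maximum likelihood (REML) via
#' [lme4::lmer()], which is robust to mildly unbalanced designs (missing
#' sessions); estimates are bounded at zero by construction and flagged
#' when they hit the bound. For perfectly balanced designs an
#' expected-mean-squares (`"ems"`) ANOVA solution is available as an exact
#' textbook cross-check; its negative solutions are truncated to zero.
#'
#' @param data long `data.frame` with columns `subject`, `day` (or
#'   `test_day`), `side`, and the metric column.
#' @param value name of the metric column.
#' @param method `"reml"` (default) or `"ems"` (balanced designs only).
#' @return Object of class `"variance_components"`: named numeric vector
#'   `sigma2` with elements `subject`, `day`, `side`, `subject_day`,
#'   `subject_side`, `residual`; plus `truncated` flags, `method`, and the
#'   facet sizes `n_subjects`, `n_days`, `n_sides`.
#' @export
variance_components <- function(data, value = "value",
                                method = c("reml", "ems")) {
  method <- match.arg(method)
  if (!"day" %in% names(data) && "test_day" %in% names(data))
    data$day <- data$test_day
  need <- c("subject", "day", "side", value)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- data.frame(subject = factor(data$subject),
                  day = factor(data$day),
                  side = factor(data$side),
                  y = as.numeric(data[[value]]))
  d <- d[stats::complete.cases(d), ]
  n_subj <- nlevels(droplevels(d$subject))
  n_days <- nlevels(droplevels(d$day))
  n_sides <- nlevels(droplevels(d$side))
  if (n_subj < 2) stop("need at least 2 subjects", call. = FALSE)
  if (n_days < 2 && n_sides < 2)
    stop(paste("design with a single day and a single side cannot separate",
               "measurement-error facets"), call. = FALSE)

  comp_names <- c("subject", "day", "side", "subject_day", "subject_side",
                  "residual")
  sigma2 <- stats::setNames(rep(0, 6), comp_names)

  if (method == "reml") {
    terms <- c("(1 | subject)",
               if (n_days > 1) "(1 | day)",
               if (n_sides > 1) "(1 | side)",
               if (n_days > 1) "(1 | subject:day)",
               if (n_sides > 1) "(1 | subject:side)")
    form <- stats::as.formula(paste("y ~ 1 +", paste(terms, collapse = " + ")))
    fit <- suppressMessages(lme4::lmer(
      form, data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    key <- c(subject = "subject", day = "day", side = "side",
             subject_day = "subject:day", subject_side = "subject:side",
             residual = "Residual")
    for (nm in names(key)) {
      row <- vc$grp == key[[nm]]
      if (any(row)) sigma2[nm] <- vc$vcov[row][1]
    }
  } else {
    tab <- table(d$subject, d$day, d$side)
    if (length(unique(as.vector(tab))) != 1L || any(tab == 0))
      stop("EMS estimation requires a balanced, fully crossed design",
           call. = FALSE)
    if (unique(as.vector(tab)) != 1L)
      stop("EMS solution implemented for one observation per cell",
           call. = FALSE)
    P <- n_subj; D <- n_days; S <- n_sides
    av <- stats::aov(y ~ subject + day + side + subject:day + subject:side,
                     data = d)
    ms <- summary(av)[[1]][["Mean Sq"]]
    terms_av <- trimws(rownames(summary(av)[[1]]))
    ms <- stats::setNames(ms, terms_av)
    ms_e <- ms[["Residuals"]]
    # expected mean squares for the all-random crossed model
    s_pd <- (ms[["subject:day"]] - ms_e) / S
    s_ps <- (ms[["subject:side"]] - ms_e) / D
    s_p <- (ms[["subject"]] - ms_e - S * s_pd - D * s_ps) / (D * S)
    s_d <- (ms[["day"]] - ms_e - S * s_pd) / (P * S)
    s_s <- (ms[["side"]] - ms_e - D * s_ps) / (P * D)
    sigma2[] <- c(s_p, s_d, s_s, s_pd, s_ps, ms_e)
  }
  truncated <- sigma2 < 1e-10 | sigma2 < 0
  sigma2 <- pmax(sigma2, 0)
  structure(list(sigma2 = sigma2, truncated = truncated, method = method,
                 n_subjects = n_subj, n_days = n_days, n_sides = n_sides),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, digits = 4, ...) {
  cat(sprintf("Variance components (%s; %d subjects x %d days x %d sides)\n",
              toupper(x$method), x$n_subjects, x$n_days, x$n_sides))
  for (nm in names(x$sigma2))
    cat(sprintf("  %-13s %s%s\n", nm, format(x$sigma2[[nm]], digits = digits),
                if (x$truncated[[nm]]) " (truncated at 0)" else ""))
  invisible(x)
}

#' Dependability coefficient and absolute SEM
#'
#' Absolute-agreement generalizability of the measurement protocol. The
#' absolute error variance for a design averaging over `n_days` days and
#' `n_sides` sides is
#' \deqn{\sigma^2_{abs} = \sigma^2_d/n_d + \sigma^2_s/n_s +
#'   \sigma^2_{pd}/n_d + \sigma^2_{ps}/n_s + \sigma^2_{res}/(n_d n_s)}
#' giving the dependability coefficient
#' \eqn{D = \sigma^2_p / (\sigma^2_p + \sigma^2_{abs})} (an
#' absolute-agreement intraclass correlation) and the absolute standard
#' error of measurement \eqn{SEM = \sqrt{\sigma^2_{abs}}}. Defaults
#' (`n_days = n_sides = 1`) describe a single observation, the usual
#' reporting convention.
#'
#' @param components a `"variance_components"` object, or a named numeric
#'   vector with the six component names.
#' @param n_days,n_sides number of days/sides averaged in the decision
#'   study.
#' @return Object of class `"reliability_report"`: `components`, `D`,
#'   `sem_abs`, `error_variance`, `n_days`, `n_sides`.
#' @export
dependability <- function(components, n_days = 1, n_sides = 1) {
  if (inherits(components, "variance_components")) {
    vc <- components$sigma2
  } else {
    vc <- components
  }
  need <- c("subject", "day", "side", "subject_day", "subject_side",
            "residual")
  if (!all(need %in% names(vc)))
    stop("components must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(vc < 0)) stop("variance components must be >= 0", call. = FALSE)
  if (n_days < 1 || n_sides < 1) stop("n_days and n_sides must be >= 1",
                                      call. = FALSE)
  err <- vc[["day"]] / n_days + vc[["side"]] / n_sides +
    vc[["subject_day"]] / n_days + vc[["subject_side"]] / n_sides +
    vc[["residual"]] / (n_days * n_sides)
  if (vc[["subject"]] + err <= 0)
    stop("all variance components are zero; D is undefined", call. = FALSE)
  structure(list(components = vc,
                 D = vc[["subject"]] / (vc[["subject"]] + err),
                 sem_abs = sqrt(err),
                 error_variance = unname(err),
                 n_days = n_days, n_sides = n_sides),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, digits = 3, ...) {
  cat(sprintf("Dependability (n_days = %g, n_sides = %g)\n",
              x$n_days, x$n_sides))
  cat(sprintf("  D = %s, absolute SEM = %s\n",
              format(x$D, digits = digits),
              format(x$sem_abs, digits = digits)))
  invisible(x)
}

#' Grouped reliability table
#'
#' Convenience driver reproducing the usual reporting layout: for each
#' group (e.g. age subgroup) and each metric column, estimate variance
#' components and single-observation dependability.
#'
#' @param data long `data.frame` with `subject`, `day`/`test_day`, `side`,
#'   a `group` column (optional) and metric columns.
#' @param metrics character vector of metric column names.
#' @param group optional name of a grouping column; `NA` rows are skipped.
#' @param method passed to [variance_components()].
#' @return `data.frame` with columns `metric`, `group`, `D`, `sem_abs`.
#' @export
reliability_table <- function(data, metrics, group = NULL,
                              method = "reml") {
  groups <- if (is.null(group)) list(all = rep(TRUE, nrow(data)))
  else split(seq_len(nrow(data)), data[[group]])
  rows <- list()
  for (g in names(groups)) {
    sub <- data[groups[[g]], , drop = FALSE]
    for (m in metrics) {
      vc <- variance_components(sub, value = m, method = method)
      rep_ <- dependability(vc)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = g, D = rep_$D, sem_abs = rep_$sem_abs,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
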