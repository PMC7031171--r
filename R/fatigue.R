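#' Fit the median-frequency fatigue regression for one electrode
#'
#' Ordinary least squares of median frequency on time over the non-excluded
#' points of the analysis window. The intercept is evaluated at the window
#' start (3 s at defaults), representing the initial spectral content
#' ("onset MF"); the slope in Hz/s is additionally normalized to the onset,
#' `slope_norm = 100 * slope_hz_s / intercept_hz`, giving the fatigue rate
#' in %/s. More negative slopes indicate faster spectral compression,
#' i.e. more fatigue.
#'
#' @param series an `"mf_series"` from [mf_series()].
#' @return Object of class `"fatigue_fit"` with elements `electrode`,
#'   `intercept_hz`, `slope_hz_s`, `slope_norm`, `n_points`, `r2`,
#'   `usable`, and the fitted data (`times`, `mf`) for the methods.
#' @seealso [summarize_fatigue()], [slope_vs_zero_test()]
#' @export
fatigue_fit <- function(series) {
  stopifnot(inherits(series, "mf_series"))
  ok <- !series$excluded & !is.na(series$mf)
  if (sum(ok) < 4L)
    stop("fewer than 4 usable MF points; fatigue fit is not defined",
         call. = FALSE)
  t_rel <- series$times[ok] - series$window_start
  y <- series$mf[ok]
  fit <- stats::lm.fit(cbind(1, t_rel), y)
  b <- unname(fit$coefficients)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(electrode = series$electrode,
                 intercept_hz = b[1],
                 slope_hz_s = b[2],
                 slope_norm = 100 * b[2] / b[1],
                 n_points = sum(ok),
                 r2 = r2,
                 usable = series$usable,
                 window_start = series$window_start,
                 times = series$times[ok],
                 mf = y),
            class = "fatigue_fit")
}

#' @export
print.fatigue_fit <- function(x, digits = 4, ...) {
  cat(sprintf("MF fatigue fit [%s]\n", x$electrode %||% "?"))
  cat(sprintf("  onset MF %s Hz, slope %s Hz/s (%s %%/s), n = %d, r2 = %s\n",
              format(x$intercept_hz, digits = digits),
              format(x$slope_hz_s, digits = digits),
              format(x$slope_norm, digits = digits),
              x$n_points, format(x$r2, digits = 3)))
  invisible(x)
}

#' @export
coef.fatigue_fit <- function(object, ...) {
  c(intercept_hz = object$intercept_hz, slope_hz_s = object$slope_hz_s,
    slope_norm = object$slope_norm)
}

#' @export
predict.fatigue_fit <- function(object, times = object$times, ...) {
  object$intercept_hz +
    object$slope_hz_s * (times - object$window_start)
}

#' @export
residuals.fatigue_fit <- function(object, ...) {
  object$mf - predict(object)
}

#' @export
plot.fatigue_fit <- function(x, ...) {
  plot(x$times, x$mf, xlab = "time (s)", ylab = "median frequency (Hz)",
       main = sprintf("%s: %.3f %%/s", x$electrode %||% "MF", x$slope_norm),
       ...)
  graphics::abline(a = x$intercept_hz - x$slope_hz_s * x$window_start,
                   b = x$slope_hz_s, lty = 2)
  invisible(x)
}

#' Aggregate the six electrode fits of one recording
#'
#' Builds the two standard aggregates: `all` (arithmetic mean of the
#' normalized slopes and of the onsets across usable electrodes) and
#' `most_negative` (the electrode with the smallest normalized slope, ties
#' broken by canonical electrode order, L5 left first).
#'
#' @param fits list of six `"fatigue_fit"`s (one per label), or fewer if
#'   some electrodes were unusable -- then `all` is computed over the
#'   usable subset and the count reported.
#' @return Object of class `"fatigue_summary"` with `fits` (named by
#'   electrode), `all_mean` (list: `slope_norm`, `intercept_hz`, `n`),
#'   `most_negative` (a `"fatigue_fit"`), and `usable` flags.
#' @export
summarize_fatigue <- function(fits) {
  if (inherits(fits, "fatigue_fit")) fits <- list(fits)
  labs <- vapply(fits, function(f) f$electrode %||% NA_character_,
                 character(1))
  if (anyNA(labs) || anyDuplicated(labs) ||
      length(setdiff(labs, semg_labels())))
    stop("fits must carry unique canonical electrode labels", call. = FALSE)
  names(fits) <- labs
  # canonical order, missing electrodes are treated as unusable
  fits <- fits[intersect(semg_labels(), labs)]
  usable <- vapply(fits, function(f) isTRUE(f$usable), logical(1))
  if (!any(usable)) stop("no usable electrode fits", call. = FALSE)
  use <- fits[usable]
  slopes <- vapply(use, function(f) f$slope_norm, numeric(1))
  onsets <- vapply(use, function(f) f$intercept_hz, numeric(1))
  most_neg <- use[[which.min(slopes)]]  # which.min keeps first on ties
  structure(list(fits = fits,
                 all_mean = list(slope_norm = mean(slopes),
                                 intercept_hz = mean(onsets),
                                 n = length(use)),
                 most_negative = most_neg,
                 usable = usable),
            class = "fatigue_summary")
}

#' @export
print.fatigue_summary <- function(x, ...) {
  cat("MF fatigue summary\n")
  for (f in x$fits)
    cat(sprintf("  %-9s onset %7.2f Hz  slope %8.4f %%/s%s\n",
                f$electrode, f$intercept_hz, f$slope_norm,
                if (isTRUE(f$usable)) "" else "  [unusable]"))
  cat(sprintf("  all (n=%d): onset %.2f Hz, slope %.4f %%/s\n",
              x$all_mean$n, x$all_mean$intercept_hz, x$all_mean$slope_norm))
  cat(sprintf("  most negative: %s (%.4f %%/s)\n",
              x$most_negative$electrode, x$most_negative$slope_norm))
  invisible(x)
}

#' Tidy table of fatigue fits
#' @param x a `"fatigue_summary"` or list of `"fatigue_fit"`s.
#' @param recording optional recording identifier.
#' @return `data.frame` with one row per electrode plus the `all` and
#'   `most_negative` aggregates.
#' @export
fatigue_table <- function(x, recording = NA_character_) {
  if (inherits(x, "fatigue_summary")) {
    rows <- lapply(x$fits, function(f)
      data.frame(recording = recording, electrode = f$electrode,
                 intercept_hz = f$intercept_hz, slope_hz_s = f$slope_hz_s,
                 slope_norm = f$slope_norm, n_points = f$n_points,
                 r2 = f$r2, usable = isTRUE(f$usable),
                 stringsAsFactors = FALSE))
    agg <- data.frame(
      recording = recording,
      electrode = c("all", "most_negative"),
      intercept_hz = c(x$all_mean$intercept_hz,
                       x$most_negative$intercept_hz),
      slope_hz_s = c(NA_real_, x$most_negative$slope_hz_s),
      slope_norm = c(x$all_mean$slope_norm, x$most_negative$slope_norm),
      n_points = c(x$all_mean$n, x$most_negative$n_points),
      r2 = NA_real_, usable = TRUE, stringsAsFactors = FALSE)
    out <- rbind(do.call(rbind, rows), agg)
    rownames(out) <- NULL
    return(out)
  }
  do.call(rbind, lapply(x, function(f)
    fatigue_table(summarize_fatigue(list(f)), recording)))
}

#' Test whether a subgroup's fatigue slopes differ from zero
#'
#' One-sample t-test of normalized slopes against zero. Significance is
#' judged against a Bonferroni-corrected threshold for the standard family
#' of 20 tests (5 electrode aggregates x 4 age/sex subgroups), i.e.
#' 0.05 / 20 = 0.0025.
#'
#' @param slopes numeric vector of normalized slopes (%/s) for one
#'   subgroup and electrode aggregate (>= 3 values).
#' @param electrode optional label carried into the result.
#' @param n_tests size of the Bonferroni family.
#' @param family_alpha family-wise significance level.
#' @return List of class `"slope_test"`: `t`, `df`, `p`, `threshold`,
#'   `significant`, `mean_slope`, `electrode`.
#' @export
slope_vs_zero_test <- function(slopes, electrode = NULL, n_tests = 20,
                               family_alpha = 0.05) {
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) < 3L)
    stop("need at least 3 slopes for the one-sample test", call. = FALSE)
  if (stats::sd(slopes) == 0) {
    if (all(slopes == 0)) {
      res <- list(t = 0, df = length(slopes) - 1L, p = 1)
    } else {
      stop("zero variance in slopes; t-test degenerate", call. = FALSE)
    }
  } else {
    ht <- stats::t.test(slopes, mu = 0)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  thr <- family_alpha / n_tests
  structure(c(res, list(threshold = thr,
                        significant = res$p < thr,
                        mean_slope = mean(slopes),
                        n = length(slopes),
                        electrode = electrode)),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf(paste0("slope vs zero [%s]: mean %.4f %%/s, t(%d) = %.2f, ",
                     "p = %.3g (%ssignificant at %.4f)\n"),
              x$electrode %||% "all", x$mean_slope, x$df, x$t, x$p,
              if (x$significant) "" else "not ", x$threshold))
  invisible(x)
}
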