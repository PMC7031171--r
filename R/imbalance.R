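#' Sample-by-sample right/left ratio of two MF series
#'
#' Element-wise ratio (right divided by left) over the jointly non-excluded
#' points of two median-frequency series sharing the same time grid; with
#' default parameters this yields up to 54 ratios over the 27-s window.
#' A point excluded on either side invalidates the paired ratio sample.
#'
#' @param right,left `"mf_series"` objects for the right and left
#'   electrodes of one lumbar level.
#' @return List of class `"ratio_series"`: `times`, `ratio`, `n`, `level`.
#' @export
ratio_series <- function(right, left) {
  stopifnot(inherits(right, "mf_series"), inherits(left, "mf_series"))
  if (length(right$times) != length(left$times) ||
      max(abs(right$times - left$times)) > 1e-9)
    stop("right and left series are not on the same time grid",
         call. = FALSE)
  ok <- !right$excluded & !left$excluded & !is.na(right$mf) & !is.na(left$mf)
  if (any(left$mf[ok] <= 0))
    stop("non-positive left-side MF value; ratio undefined", call. = FALSE)
  level <- NULL
  if (!is.null(right$electrode))
    level <- sub("_(left|right)$", "", right$electrode)
  structure(list(times = right$times[ok],
                 ratio = right$mf[ok] / left$mf[ok],
                 n = sum(ok),
                 level = level),
            class = "ratio_series")
}

#' Symmetric corrected ratio transform
#'
#' Maps a raw right/left ratio `r > 0` onto a signed percentage `R` that is
#' centred at zero for perfect symmetry and antisymmetric under side swap:
#' `R(1) = 0`, `R(r) = -R(1/r)`, monotone increasing in `r`, positive when
#' right > left. Two transforms are provided:
#' * `"percent_difference"` (default): `R = 100 (r - 1)` for `r >= 1` and
#'   `-100 (1/r - 1)` for `r < 1` -- the percent difference of the larger
#'   side relative to the smaller.
#' * `"log"`: `R = 100 log(r)`, the log-ratio on a percent-like scale.
#'
#' @param r positive raw ratio(s).
#' @param method transform choice.
#' @return Corrected ratio(s) in percent.
#' @export
symmetric_ratio <- function(r, method = c("percent_difference", "log")) {
  method <- match.arg(method)
  if (any(!is.finite(r) | r <= 0))
    stop("raw ratios must be positive and finite", call. = FALSE)
  switch(method,
         percent_difference = ifelse(r >= 1, 100 * (r - 1),
                                     -100 * (1 / r - 1)),
         log = 100 * log(r))
}

#' Segmental and global left/right imbalance of one recording
#'
#' For each lumbar level the segmental imbalance is the time-mean of the
#' symmetric corrected ratio series (positive = right > left). The two
#' global parameters aggregate across levels: the *uncompensated* imbalance
#' is the mean of the absolute segmental values (total imbalance regardless
#' of direction), the *compensated* imbalance is the mean of the signed
#' values (net lateralization after opposite-side segments cancel). By
#' construction `uncompensated >= |compensated|`.
#'
#' @param ratios named list of `"ratio_series"` (names `L5`, `L2`, `L1`,
#'   or any order; all three levels required), from [ratio_series()].
#' @param method transform passed to [symmetric_ratio()].
#' @return Object of class `"imbalance_summary"`: `segmental` (named %,
#'   signed), `uncompensated` (%), `compensated` (%), `method`.
#' @export
imbalance_summary <- function(ratios,
                              method = c("percent_difference", "log")) {
  method <- match.arg(method)
  if (is.null(names(ratios)) || !all(nzchar(names(ratios))))
    names(ratios) <- vapply(ratios, function(r) r$level %||% NA_character_,
                            character(1))
  miss <- setdiff(semg_levels(), names(ratios))
  if (length(miss))
    stop("missing lumbar level(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ratios <- ratios[semg_levels()]
  segmental <- vapply(ratios, function(rs) {
    stopifnot(inherits(rs, "ratio_series"))
    if (rs$n < 1L) stop("empty ratio series", call. = FALSE)
    mean(symmetric_ratio(rs$ratio, method))
  }, numeric(1))
  structure(list(segmental = segmental,
                 uncompensated = mean(abs(segmental)),
                 compensated = mean(segmental),
                 method = method),
            class = "imbalance_summary")
}

#' @export
print.imbalance_summary <- function(x, ...) {
  cat("Left/right MF imbalance (positive = right > left)\n")
  for (lv in names(x$segmental))
    cat(sprintf("  %s: %+.2f %%\n", lv, x$segmental[[lv]]))
  cat(sprintf("  uncompensated: %.2f %%   compensated: %+.2f %%\n",
              x$uncompensated, x$compensated))
  invisible(x)
}

#' Tidy table of an imbalance summary
#' @param x an `"imbalance_summary"`.
#' @param recording optional recording identifier.
#' @return One-row-per-level `data.frame` plus the two global parameters.
#' @export
imbalance_table <- function(x, recording = NA_character_) {
  data.frame(recording = recording,
             level = c(names(x$segmental), "uncompensated", "compensated"),
             imbalance_pct = c(unname(x$segmental), x$uncompensated,
                               x$compensated),
             stringsAsFactors = FALSE)
}
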