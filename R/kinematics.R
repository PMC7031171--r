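#' Trunk-angle series and quality-control metrics from the accelerometer
#'
#' The dynamometer lever arm carries a tri-axial accelerometer whose
#' selected axis reads the gravity component `g sin(angle)`; with traces in
#' g units the inclination proxy is simply `angle(t) = asin(acc(t))`.
#' Samples marginally outside |1| (sensor noise, quantization) are clamped;
#' persistent excursions beyond `1 + angle_clamp_tol` raise a sensor-range
#' error. Two quality-control metrics summarize the mechanics of the test:
#' the onset angle (mean over the first `onset_window` seconds) and the
#' drift rate (OLS slope of angle on time over the whole trace), which
#' should be near zero when the position was held.
#'
#' @param accel a `"semg_recording"`, a 3-column accelerometer matrix with
#'   columns `x_g`/`y_g`/`z_g`, or a numeric vector for the selected axis
#'   (g units).
#' @param fs sampling rate in Hz (taken from the recording if given one).
#' @param config a [semg_config()]; supplies the axis choice and clamp
#'   tolerance.
#' @param onset_window seconds over which the onset angle is averaged.
#' @return Object of class `"trunk_angle"`: `times` (s), `angle_deg`,
#'   `onset_angle`, `drift_rate` (deg/s), `n_clamped`.
#' @export
trunk_angle <- function(accel, fs = NULL, config = semg_config(),
                        onset_window = 1) {
  if (inherits(accel, "semg_recording")) {
    if (is.null(accel$accel))
      stop("recording has no accelerometer trace", call. = FALSE)
    fs <- accel$accel_fs
    accel <- accel$accel
  }
  if (is.matrix(accel)) {
    col <- paste0(config$angle_axis, "_g")
    if (!col %in% colnames(accel))
      stop("accelerometer matrix has no column ", col, call. = FALSE)
    z <- accel[, col]
  } else {
    z <- as.numeric(accel)
  }
  if (is.null(fs)) stop("fs is required for a bare accelerometer vector",
                        call. = FALSE)
  tol <- config$angle_clamp_tol
  out_of_range <- abs(z) > 1 + tol
  if (mean(out_of_range) > 0.01)
    stop(sprintf(paste0("%.1f%% of accelerometer samples exceed the sensor ",
                        "range |1 + %g| g; trace cannot be an inclination ",
                        "proxy"), 100 * mean(out_of_range), tol),
         call. = FALSE)
  n_clamped <- sum(z > 1 | z < -1)
  z <- pmin(1, pmax(-1, z))
  angle <- asin(z) * 180 / pi
  times <- (seq_along(z) - 1L) / fs
  onset <- mean(angle[times < onset_window])
  drift <- unname(stats::lm.fit(cbind(1, times), angle)$coefficients[2])
  structure(list(times = times, angle_deg = angle,
                 onset_angle = onset, drift_rate = drift,
                 n_clamped = n_clamped, fs = fs),
            class = "trunk_angle")
}

#' @export
print.trunk_angle <- function(x, ...) {
  cat(sprintf(paste0("Trunk angle: onset %.2f deg, drift %.4f deg/s ",
                     "(%d samples, %d clamped)\n"),
              x$onset_angle, x$drift_rate, length(x$angle_deg), x$n_clamped))
  invisible(x)
}

#' @export
plot.trunk_angle <- function(x, ...) {
  plot(x$times, x$angle_deg, type = "l", xlab = "time (s)",
       ylab = "inclination (deg)", ...)
  graphics::abline(a = x$onset_angle, b = 0, lty = 3)
  invisible(x)
}
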