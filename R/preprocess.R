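#' Restrict a channel to the analysis window
#'
#' Drops the unstable first seconds of the sustained contraction (the force
#' ramp and posture adjustments) and anything beyond the analysis end. The
#' channel remembers its own time origin through the `t0` attribute, so
#' trimming an already-trimmed channel is the identity.
#'
#' @param x numeric channel vector with attributes `fs` and `t0`, as
#'   returned by [generate_semg_channel()] or [semg_channel()].
#' @param config a [semg_config()].
#' @return The windowed channel with updated `t0`.
#' @export
trim_window <- function(x, config = semg_config()) {
  fs <- channel_fs(x)
  t0 <- channel_t0(x)
  end_avail <- t0 + length(x) / fs
  if (end_avail < config$analysis_end - 1e-9) {
    if (!config$allow_short)
      stop(sprintf(paste0("recording ends at %.2f s but the analysis window ",
                          "extends to %g s; set allow_short = TRUE to ",
                          "analyse the available data"),
                   end_avail, config$analysis_end), call. = FALSE)
    warning(sprintf("short recording: analysing [%g, %.2f) s only",
                    max(config$trim_start, t0), end_avail), call. = FALSE)
  }
  start_s <- max(config$trim_start, t0)
  end_s <- min(config$analysis_end, end_avail)
  if (start_s >= end_s) stop("empty analysis window", call. = FALSE)
  i0 <- round((start_s - t0) * fs) + 1L
  i1 <- round((end_s - t0) * fs)
  out <- x[i0:i1]
  attributes(out) <- NULL
  attr(out, "fs") <- fs
  attr(out, "t0") <- start_s
  attr(out, "label") <- attr(x, "label")
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the configured band-pass (default 20--500 Hz, 4th order) forward
#' and backward ([signal::filtfilt()]), giving zero phase shift so epoch
#' timing is preserved; the effective magnitude response is that of twice
#' the nominal order.
#'
#' @param x numeric channel vector with attribute `fs`.
#' @param config a [semg_config()].
#' @return Filtered channel, attributes preserved.
#' @export
bandpass_filter <- function(x, config = semg_config()) {
  fs <- channel_fs(x)
  if (config$lowpass_cutoff >= fs / 2)
    stop("lowpass cutoff at or above Nyquist for this channel", call. = FALSE)
  bf <- signal::butter(config$filter_order,
                       c(config$highpass_cutoff, config$lowpass_cutoff) /
                         (fs / 2),
                       type = "pass")
  y <- signal::filtfilt(bf, as.numeric(x))
  attr(y, "fs") <- fs
  attr(y, "t0") <- channel_t0(x)
  attr(y, "label") <- attr(x, "label")
  y
}

#' Flag artifact-contaminated epochs
#'
#' Scans the channel on the same epoch grid used for spectral estimation
#' and flags an epoch when (a) any sample reaches `clip_fraction` of the
#' ADC full scale (`clip_level`), or (b) the epoch RMS exceeds
#' `rms_outlier_factor` times the median epoch RMS (movement/contact
#' artifacts). Flagged epochs later appear as excluded points in the MF
#' series; they are reported, never interpolated.
#'
#' @param x trimmed (and typically filtered) channel vector.
#' @param config a [semg_config()].
#' @return List of class `"artifact_scan"` with elements `x` (unchanged
#'   channel), `excluded` (logical per epoch), `fraction_excluded`, and
#'   `usable` (`FALSE` when more than `max_excluded_fraction` of epochs are
#'   contaminated).
#' @export
remove_artifacts <- function(x, config = semg_config()) {
  fs <- channel_fs(x)
  ep <- epoch_grid(length(x), fs, config)
  if (ep$n < 1L) stop("channel shorter than one epoch", call. = FALSE)
  clip_thr <- config$clip_fraction * config$clip_level
  rms <- numeric(ep$n)
  clipped <- logical(ep$n)
  for (i in seq_len(ep$n)) {
    seg <- x[ep$start[i]:(ep$start[i] + ep$len - 1L)]
    rms[i] <- sqrt(mean(seg^2))
    clipped[i] <- any(abs(seg) >= clip_thr)
  }
  outlier <- rms > config$rms_outlier_factor * stats::median(rms)
  excluded <- clipped | outlier
  frac <- mean(excluded)
  structure(list(x = x,
                 excluded = excluded,
                 clipped = clipped,
                 rms_outlier = outlier,
                 fraction_excluded = frac,
                 usable = frac <= config$max_excluded_fraction),
            class = "artifact_scan")
}

#' Preprocess one SEMG channel
#'
#' Trim to the analysis window, band-pass filter, then scan for artifacts;
#' the standard chain applied before spectral analysis.
#'
#' @param x raw channel vector with `fs`/`t0` attributes.
#' @param config a [semg_config()].
#' @return An `"artifact_scan"` whose `x` is the trimmed, filtered channel.
#' @export
preprocess_channel <- function(x, config = semg_config()) {
  remove_artifacts(bandpass_filter(trim_window(x, config), config), config)
}

#' Wrap a plain numeric vector as an SEMG channel
#'
#' @param x numeric samples in volts.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds from contraction onset.
#' @param label optional electrode label.
#' @return `x` with `fs`, `t0` and `label` attributes.
#' @export
semg_channel <- function(x, fs, t0 = 0, label = NULL) {
  x <- as.numeric(x)
  attr(x, "fs") <- fs
  attr(x, "t0") <- t0
  attr(x, "label") <- label
  x
}

channel_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) stop("channel has no 'fs' attribute; see semg_channel()",
                        call. = FALSE)
  fs
}

channel_t0 <- function(x) {
  t0 <- attr(x, "t0")
  if (is.null(t0)) 0 else t0
}

# Epoch grid shared by artifact scanning and spectral estimation:
# epoch length and hop in samples, start indices.
epoch_grid <- function(n_samples, fs, config) {
  len <- round(config$epoch_s * fs)
  hop <- max(1L, round(len * (1 - config$epoch_overlap)))
  n <- if (n_samples < len) 0L else (n_samples - len) %/% hop + 1L
  list(len = len, hop = hop, n = n,
       start = if (n > 0L) (seq_len(n) - 1L) * hop + 1L else integer(0))
}
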