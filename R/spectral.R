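#' Median frequency of a power spectrum
#'
#' The frequency at which cumulative power reaches half of the total power
#' within `band`. The cumulative distribution is interpolated linearly
#' through the mid-bin points (cumulative power up to the centre of each
#' bin), so a spectrum that is symmetric about some frequency has exactly
#' that frequency as its median -- e.g. a flat band over 20--500 Hz gives
#' 260 Hz.
#'
#' @param freq numeric vector of spectral bin frequencies (Hz, increasing).
#' @param power non-negative spectral power per bin.
#' @param band length-2 numeric, frequency band restricting the
#'   computation; defaults to the full extent of `freq`.
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(freq, power, band = range(freq)) {
  stopifnot(length(freq) == length(power))
  if (any(power < 0)) stop("power must be non-negative", call. = FALSE)
  keep <- freq >= band[1] & freq <= band[2]
  f <- freq[keep]
  p <- power[keep]
  if (length(f) < 1L || sum(p) <= 0)
    stop("zero total power in band; median frequency undefined",
         call. = FALSE)
  total <- sum(p)
  # cumulative power evaluated at each bin centre (half of the bin's own
  # mass counted), piecewise-linear in between
  cum_mid <- cumsum(p) - p / 2
  half <- total / 2
  i <- findInterval(half, cum_mid)
  if (i <= 0L) return(f[1])
  if (i >= length(f)) return(f[length(f)])
  f[i] + (half - cum_mid[i]) / (cum_mid[i + 1L] - cum_mid[i]) *
    (f[i + 1L] - f[i])
}

#' Median-frequency time series of an SEMG channel
#'
#' Computes one Blackman-windowed periodogram per 500-ms epoch (50%
#' overlap), restricts power to the configured 20--500 Hz band, and takes
#' the spectral median of each epoch. With `mf_output = "paired2hz"`
#' (default) adjacent overlapped estimates are averaged pairwise, emitting
#' a 2 Hz series of 54 samples over the 27-s analysis window; `"raw4hz"`
#' returns every epoch estimate (4 Hz). Epochs flagged by the artifact scan
#' become excluded (`NA`) points.
#'
#' @param x a preprocessed channel (from [preprocess_channel()], an
#'   `"artifact_scan"`), or a trimmed+filtered channel vector.
#' @param config a [semg_config()].
#' @param exclude optional logical vector, one entry per raw epoch,
#'   overriding the artifact mask.
#' @param electrode electrode label for the series; defaults to the
#'   channel's `label` attribute.
#' @return An object of class `"mf_series"`: list with `electrode`, `times`
#'   (s from contraction onset, uniform grid at the output rate), `mf`
#'   (Hz, `NA` where excluded), `excluded`, `output_rate` (Hz),
#'   `window_start` and `usable` (at least 4 usable epochs).
#' @export
mf_series <- function(x, config = semg_config(), exclude = NULL,
                      electrode = NULL) {
  if (inherits(x, "artifact_scan")) {
    if (is.null(exclude)) exclude <- x$excluded
    x <- x$x
  }
  fs <- channel_fs(x)
  t0 <- channel_t0(x)
  if (is.null(electrode)) electrode <- attr(x, "label")
  ep <- epoch_grid(length(x), fs, config)
  if (ep$len > length(x))
    stop("epoch longer than the available signal", call. = FALSE)
  if (is.null(exclude)) exclude <- rep(FALSE, ep$n)
  if (length(exclude) != ep$n)
    stop("exclude mask length (", length(exclude),
         ") does not match the number of epochs (", ep$n, ")", call. = FALSE)

  w <- blackman_window(ep$len)
  nyq_bins <- ep$len %/% 2L
  freqs <- (0:nyq_bins) * fs / ep$len
  band <- c(config$highpass_cutoff, config$lowpass_cutoff)
  mf_raw <- rep(NA_real_, ep$n)
  for (i in seq_len(ep$n)) {
    if (exclude[i]) next
    seg <- x[ep$start[i]:(ep$start[i] + ep$len - 1L)]
    seg <- (seg - mean(seg)) * w
    spec <- Mod(stats::fft(seg)[1:(nyq_bins + 1L)])^2
    mf_raw[i] <- median_frequency(freqs, spec, band)
  }
  t_raw <- t0 + (ep$start - 1L) / fs + ep$len / fs / 2  # epoch centres

  if (config$mf_output == "raw4hz") {
    out_rate <- 1 / (ep$hop / fs)
    times <- t_raw
    mf <- mf_raw
    excl <- exclude
  } else {
    # average adjacent overlapped estimates pairwise: epochs (1,2), (3,4),
    # ...; a trailing unpaired epoch stands alone. Emits the 2 Hz grid.
    # An output point inherits exclusion from either constituent epoch.
    n_out <- ceiling(ep$n / 2)
    mf <- numeric(n_out)
    excl <- logical(n_out)
    for (j in seq_len(n_out)) {
      pair <- unique(c(2L * j - 1L, min(2L * j, ep$n)))
      if (any(exclude[pair])) {
        mf[j] <- NA_real_
        excl[j] <- TRUE
      } else {
        mf[j] <- mean(mf_raw[pair])
      }
    }
    hop_s <- ep$hop / fs
    # uniform grid at 1/(2*hop): nominal centre of each epoch pair
    times <- t0 + (seq_len(n_out) - 1L) * 2 * hop_s + ep$len / fs / 2 +
      hop_s / 2
    out_rate <- 1 / (2 * hop_s)
  }
  usable <- sum(!excl) >= 4L
  structure(list(electrode = electrode,
                 times = times,
                 mf = mf,
                 excluded = excl,
                 output_rate = out_rate,
                 window_start = t0,
                 usable = usable),
            class = "mf_series")
}

blackman_window <- function(n) {
  k <- seq_len(n) - 1L
  0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
}

#' @export
print.mf_series <- function(x, ...) {
  cat(sprintf("MF series [%s]: %d points @ %g Hz, %d excluded\n",
              x$electrode %||% "?", length(x$mf), x$output_rate,
              sum(x$excluded)))
  ok <- !x$excluded
  if (any(ok))
    cat(sprintf("  span %.2f-%.2f s, MF %.1f-%.1f Hz (mean %.1f)\n",
                min(x$times), max(x$times), min(x$mf[ok]), max(x$mf[ok]),
                mean(x$mf[ok])))
  if (!x$usable) cat("  UNUSABLE: fewer than 4 usable epochs\n")
  invisible(x)
}

#' @export
plot.mf_series <- function(x, ...) {
  plot(x$times, x$mf, xlab = "time (s)", ylab = "median frequency (Hz)",
       main = x$electrode %||% "MF series", ...)
  invisible(x)
}

#' Tidy data frame of one or more MF series
#' @param series an `"mf_series"` or list of them.
#' @param recording optional recording identifier column value.
#' @return `data.frame` with columns `recording`, `electrode`, `time_s`,
#'   `mf_hz`, `excluded`.
#' @export
mf_series_table <- function(series, recording = NA_character_) {
  if (inherits(series, "mf_series")) series <- list(series)
  do.call(rbind, lapply(series, function(s)
    data.frame(recording = recording,
               electrode = s$electrode %||% NA_character_,
               time_s = s$times, mf_hz = s$mf, excluded = s$excluded,
               stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
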