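#' Canonical electrode labels
#'
#' The six recording sites, ordered by lumbar level from L5 (multifidus)
#' through L2 (longissimus) to L1 (iliocostalis lumborum), left before right
#' within a level. This order is used for channel storage, for reporting,
#' and as the tie-break order when selecting the most negative electrode.
#'
#' @return Character vector of the six labels.
#' @export
semg_labels <- function() {
  c("L5_left", "L5_right", "L2_left", "L2_right", "L1_left", "L1_right")
}

#' Lumbar levels covered by the electrode montage
#' @return Character vector `c("L5", "L2", "L1")`.
#' @export
semg_levels <- function() c("L5", "L2", "L1")

#' Analysis configuration
#'
#' Bundles every tunable parameter of the processing chain. All defaults
#' correspond to the standard protocol for a 30-s sustained back extension
#' at 80% MVC: the first 3 s of the task are skipped, SEMG is band-passed
#' 20--500 Hz, and median frequency is estimated from Blackman-windowed
#' 500-ms epochs with 50% overlap, then emitted as a 2 Hz series of 54
#' samples spanning the 27-s analysis window.
#'
#' @param semg_fs SEMG sampling rate in Hz.
#' @param accel_fs accelerometer sampling rate in Hz.
#' @param trim_start seconds skipped at the start of the contraction.
#' @param analysis_end end of the analysis window in seconds from onset.
#' @param highpass_cutoff,lowpass_cutoff Butterworth band edges in Hz.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective attenuation is that of twice this order).
#' @param epoch_s spectral epoch length in seconds.
#' @param epoch_overlap fractional overlap between successive epochs.
#' @param mf_output `"paired2hz"` averages adjacent overlapped epochs into a
#'   2 Hz, 54-sample series; `"raw4hz"` returns the raw 4 Hz epoch series.
#' @param clip_level ADC full-scale amplitude in volts; samples at or above
#'   99% of it mark their epoch as clipped.
#' @param clip_fraction fraction of full scale treated as clipping.
#' @param rms_outlier_factor epochs whose RMS exceeds this multiple of the
#'   median epoch RMS are excluded as artifacts.
#' @param max_excluded_fraction above this fraction of excluded epochs the
#'   channel is flagged unusable.
#' @param allow_short if `TRUE`, recordings shorter than `analysis_end` are
#'   analysed up to the available end with a warning instead of an error.
#' @param imbalance_transform symmetric ratio transform, see
#'   [symmetric_ratio()].
#' @param angle_axis accelerometer axis used as the gravity/inclination
#'   proxy.
#' @param angle_clamp_tol tolerance beyond |1 g| before a sample counts as
#'   out of sensor range.
#'
#' @return A list of class `"semg_config"`.
#' @export
semg_config <- function(semg_fs = 2000,
                        accel_fs = 160,
                        trim_start = 3,
                        analysis_end = 30,
                        highpass_cutoff = 20,
                        lowpass_cutoff = 500,
                        filter_order = 4,
                        epoch_s = 0.5,
                        epoch_overlap = 0.5,
                        mf_output = c("paired2hz", "raw4hz"),
                        clip_level = 0.011,
                        clip_fraction = 0.99,
                        rms_outlier_factor = 5,
                        max_excluded_fraction = 0.5,
                        allow_short = FALSE,
                        imbalance_transform = c("percent_difference", "log"),
                        angle_axis = c("z", "x", "y"),
                        angle_clamp_tol = 0.02) {
  cfg <- list(
    semg_fs = semg_fs,
    accel_fs = accel_fs,
    trim_start = trim_start,
    analysis_end = analysis_end,
    highpass_cutoff = highpass_cutoff,
    lowpass_cutoff = lowpass_cutoff,
    filter_order = filter_order,
    epoch_s = epoch_s,
    epoch_overlap = epoch_overlap,
    mf_output = match.arg(mf_output),
    clip_level = clip_level,
    clip_fraction = clip_fraction,
    rms_outlier_factor = rms_outlier_factor,
    max_excluded_fraction = max_excluded_fraction,
    allow_short = allow_short,
    imbalance_transform = match.arg(imbalance_transform),
    angle_axis = match.arg(angle_axis),
    angle_clamp_tol = angle_clamp_tol
  )
  class(cfg) <- "semg_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "semg_config"))
  if (!(cfg$trim_start >= 0 && cfg$trim_start < cfg$analysis_end))
    stop("need 0 <= trim_start < analysis_end", call. = FALSE)
  if (!(cfg$highpass_cutoff > 0 &&
        cfg$highpass_cutoff < cfg$lowpass_cutoff))
    stop("need 0 < highpass_cutoff < lowpass_cutoff", call. = FALSE)
  if (cfg$lowpass_cutoff >= cfg$semg_fs / 2)
    stop("lowpass_cutoff must lie strictly below the SEMG Nyquist frequency (",
         cfg$semg_fs / 2, " Hz)", call. = FALSE)
  if (cfg$epoch_s <= 0 || cfg$epoch_overlap < 0 || cfg$epoch_overlap >= 1)
    stop("invalid epoch parameters", call. = FALSE)
  invisible(cfg)
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [semg_config()]; unknown keys are an error
#' so that typos do not silently fall back to defaults.
#'
#' @param path file path to a `.yaml`/`.yml` or `.json` configuration.
#' @return A validated `"semg_config"` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(semg_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(semg_config, raw)
}

#' @export
print.semg_config <- function(x, ...) {
  cat("SEMG analysis configuration\n")
  cat(sprintf("  window: [%g, %g) s, band: %g-%g Hz (Butterworth order %d, zero-phase)\n",
              x$trim_start, x$analysis_end, x$highpass_cutoff,
              x$lowpass_cutoff, x$filter_order))
  cat(sprintf("  epochs: %g ms, %.0f%% overlap, output: %s\n",
              1000 * x$epoch_s, 100 * x$epoch_overlap, x$mf_output))
  invisible(x)
}

# Derive a stream of child seeds from one user seed, keeping everything
# below .Machine$integer.max so seeds survive integer coercion.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
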