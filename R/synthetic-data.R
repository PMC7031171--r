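#' Specification of one synthetic SEMG channel
#'
#' Describes the programmed ground truth for a single electrode site: the
#' spectral median frequency at contraction onset, its normalized linear
#' rate of decline as the muscle fatigues, and the signal/noise amplitudes.
#' The generator produces a stochastic signal whose short-time spectral
#' median tracks
#' \deqn{MF(t) = onset\_mf \cdot (1 + normalized\_slope/100 \cdot t)}
#' with `t` in seconds from contraction onset.
#'
#' @param label electrode-site label, one of [semg_labels()].
#' @param onset_mf median frequency at `t = 0`, in Hz; must lie inside the
#'   20--500 Hz analysis band.
#' @param normalized_slope normalized MF slope in %/s (typically negative;
#'   sustained high-load back extensions show roughly -0.1 to -0.4 %/s).
#' @param amplitude_rms target RMS amplitude of the myoelectric component,
#'   in volts.
#' @param noise_floor_rms RMS of the additive wide-band instrumentation
#'   noise floor, in volts.
#' @param spectral_sd spread (standard deviation, Hz) of the Gaussian-shaped
#'   power spectrum around `MF(t)`. The spectrum is symmetric, so its median
#'   equals `MF(t)` exactly, which is what makes the ground truth exact.
#'
#' @return A list of class `"channel_spec"`.
#' @export
channel_spec <- function(label,
                         onset_mf = 100,
                         normalized_slope = -0.2,
                         amplitude_rms = 1.5e-4,
                         noise_floor_rms = 7.5e-7,
                         spectral_sd = 10) {
  if (!is.character(label) || length(label) != 1L ||
      !(label %in% semg_labels()))
    stop("label must be one of: ", paste(semg_labels(), collapse = ", "),
         call. = FALSE)
  if (!(onset_mf > 20 && onset_mf < 500))
    stop("onset_mf must lie within (20, 500) Hz", call. = FALSE)
  if (amplitude_rms <= 0) stop("amplitude_rms must be > 0", call. = FALSE)
  if (noise_floor_rms < 0) stop("noise_floor_rms must be >= 0", call. = FALSE)
  if (spectral_sd <= 0) stop("spectral_sd must be > 0", call. = FALSE)
  structure(list(label = label,
                 onset_mf = onset_mf,
                 normalized_slope = normalized_slope,
                 amplitude_rms = amplitude_rms,
                 noise_floor_rms = noise_floor_rms,
                 spectral_sd = spectral_sd),
            class = "channel_spec")
}

#' Generate a synthetic SEMG channel with known median-frequency trajectory
#'
#' Synthesizes a zero-mean stochastic signal as a dense random-phase
#' multisine: `n_components` cosines whose frequency offsets are a
#' stratified sample from a Gaussian of SD `spectral_sd` centred on the
#' programmed trajectory `MF(t)`, each swept linearly so the whole spectrum
#' translates with `MF(t)`. Because the spectral shape is symmetric about
#' `MF(t)`, the programmed trajectory is the exact spectral median at every
#' instant, and the short-time spectral stage can be validated against it.
#' A white Gaussian noise floor is added on top.
#'
#' @param spec a [channel_spec()].
#' @param duration signal duration in seconds (>= 4).
#' @param fs sampling rate in Hz (>= 1024).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output. Draws are made under a local RNG state, global state is left
#'   untouched.
#' @param n_components number of multisine components.
#' @return Numeric vector of `duration * fs` samples (volts) with
#'   attributes `fs`, `t0` (= 0, seconds of the first sample relative to
#'   contraction onset) and `label`.
#' @export
generate_semg_channel <- function(spec, duration = 30, fs = 2000, seed,
                                  n_components = 200) {
  stopifnot(inherits(spec, "channel_spec"))
  if (duration < 4) stop("duration must be >= 4 s", call. = FALSE)
  if (fs < 1024) stop("fs must be >= 1024 Hz", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)

  m0 <- spec$onset_mf
  sl <- spec$normalized_slope
  half_band <- 3 * spec$spectral_sd
  mf_end <- m0 * (1 + sl / 100 * duration)
  band_lo <- min(m0, mf_end) - half_band
  band_hi <- max(m0, mf_end) + half_band
  if (mf_end <= 20 || mf_end >= fs / 2)
    stop(sprintf(paste0("programmed MF trajectory ends at %.1f Hz, outside ",
                        "(20, fs/2); reduce |normalized_slope| or duration"),
                 mf_end), call. = FALSE)
  if (band_lo <= 20 || band_hi >= min(500, fs / 2))
    stop(sprintf(paste0("programmed spectrum [%.1f, %.1f] Hz leaves the ",
                        "20-%g Hz filter band; narrow spectral_sd or the ",
                        "MF trajectory"),
                 band_lo, band_hi, min(500, fs / 2)), call. = FALSE)

  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  k <- n_components
  x <- withr::with_seed(seed, {
    # stratified Gaussian offsets: symmetric spectrum, median exactly MF(t)
    u <- (seq_len(k) - 1L + stats::runif(k)) / k
    delta <- spec$spectral_sd * stats::qnorm(u)
    theta <- stats::runif(k, 0, 2 * pi)
    amp <- spec$amplitude_rms * sqrt(2 / k)
    sig <- numeric(n)
    # instantaneous frequency of component k: m0 + delta_k + m0*sl/100 * t
    chirp <- m0 * sl / 200 * t^2
    for (i in seq_len(k)) {
      sig <- sig + amp * cos(2 * pi * ((m0 + delta[i]) * t + chirp) + theta[i])
    }
    if (spec$noise_floor_rms > 0)
      sig <- sig + stats::rnorm(n, sd = spec$noise_floor_rms)
    sig
  })
  x <- x - mean(x)
  attr(x, "fs") <- fs
  attr(x, "t0") <- 0
  attr(x, "label") <- spec$label
  x
}

#' Trunk-angle profile for synthetic recordings
#'
#' @param onset_deg lever-arm inclination at contraction onset, degrees.
#' @param drift_deg_s linear drift of the inclination, degrees per second
#'   (positive = sinking further into flexion).
#' @return List of class `"angle_profile"`.
#' @export
angle_profile <- function(onset_deg = 23, drift_deg_s = 0.05) {
  if (abs(onset_deg) >= 90) stop("onset_deg must lie in (-90, 90)",
                                 call. = FALSE)
  structure(list(onset_deg = onset_deg, drift_deg_s = drift_deg_s),
            class = "angle_profile")
}

#' Generate a complete synthetic contraction recording
#'
#' Bundles six SEMG channels (three lumbar levels, both sides) with a
#' tri-axial accelerometer trace from the dynamometer lever arm. The
#' accelerometer z-axis reads `sin(angle(t))` in g units (the gravity
#' component along the lever arm) plus Gaussian sensor noise; the x-axis
#' carries the complementary `cos(angle(t))` and y is noise only.
#'
#' @param channel_specs list of exactly six [channel_spec()]s covering all
#'   of [semg_labels()].
#' @param angle an [angle_profile()].
#' @param duration recording duration in seconds.
#' @param seed integer seed for all channels and sensor noise.
#' @param meta a [recording_meta()] (optional metadata).
#' @param semg_fs,accel_fs sampling rates in Hz.
#' @param accel_noise_sd accelerometer noise SD in g.
#' @param quantize_8bit if `TRUE`, accelerometer samples are quantized to
#'   8 bits over a +/- 1.5 g range, mirroring a low-resolution sensor.
#' @return A `"semg_recording"` object, see [new_recording()].
#' @export
generate_recording <- function(channel_specs,
                               angle = angle_profile(),
                               duration = 30,
                               seed,
                               meta = recording_meta(),
                               semg_fs = 2000,
                               accel_fs = 160,
                               accel_noise_sd = 0.01,
                               quantize_8bit = FALSE) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  labels <- vapply(channel_specs, function(s) {
    stopifnot(inherits(s, "channel_spec")); s$label
  }, character(1))
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  missing_lab <- setdiff(semg_labels(), labels)
  if (length(missing_lab))
    stop("missing channel(s): ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  stopifnot(inherits(angle, "angle_profile"))

  seeds <- derive_seeds(seed, 7L)
  ord <- match(semg_labels(), labels)
  semg <- vapply(seq_along(ord), function(i) {
    as.numeric(generate_semg_channel(channel_specs[[ord[i]]], duration,
                                     semg_fs, seed = seeds[i]))
  }, numeric(round(duration * semg_fs)))
  colnames(semg) <- semg_labels()

  na <- round(duration * accel_fs)
  ta <- (seq_len(na) - 1L) / accel_fs
  theta <- (angle$onset_deg + angle$drift_deg_s * ta) * pi / 180
  accel <- withr::with_seed(seeds[7L], {
    cbind(x_g = cos(theta) + stats::rnorm(na, sd = accel_noise_sd),
          y_g = stats::rnorm(na, sd = accel_noise_sd),
          z_g = sin(theta) + stats::rnorm(na, sd = accel_noise_sd))
  })
  if (quantize_8bit) accel <- round(accel * 127 / 1.5) * 1.5 / 127

  rec <- new_recording(semg = semg, semg_fs = semg_fs,
                       accel = accel, accel_fs = accel_fs, meta = meta)
  attr(rec, "truth") <- list(
    channels = channel_specs[ord], angle = angle, seed = seed)
  rec
}

#' Specification of a synthetic cohort with known variance structure
#'
#' Defines the generating model for a single fatigue metric observed on
#' `n_per_group` subjects in each age x sex cell over `n_days` test days and
#' both body sides:
#' \deqn{y = \mu_{cell} + p + d + s + pd + ps + \epsilon}
#' with independent Gaussian random effects for subject (`p`), day (`d`),
#' side (`s`), their interactions with subject, and residual error. This is
#' the crossed random-effects structure used by the generalizability-theory
#' reliability analysis, so estimated variance components and dependability
#' can be checked against programmed truth.
#'
#' @param n_per_group subjects per age x sex cell (>= 2).
#' @param group_means 2 x 2 numeric matrix of cell means (rows: young, old;
#'   columns: male, female), or a single number used for every cell.
#' @param variance_components named numeric vector with elements `subject`,
#'   `day`, `side`, `subject_day`, `subject_side`, `residual` (metric
#'   units squared, all >= 0). Defaults emulate a normalized-slope metric
#'   with single-observation dependability about 0.92 and absolute SEM
#'   about 0.044 %/s, typical of multi-day MF-SEMG protocols.
#' @param n_days number of test days (>= 1).
#' @param metric name of the generated metric column.
#' @param seed default seed used by [generate_cohort()].
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = 25,
                        group_means = 0,
                        variance_components = c(subject = 0.0233,
                                                day = 1e-4,
                                                side = 1e-4,
                                                subject_day = 9e-4,
                                                subject_side = 4e-4,
                                                residual = 4.4e-4),
                        n_days = 3,
                        metric = "value",
                        seed = NULL) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  need <- c("subject", "day", "side", "subject_day", "subject_side",
            "residual")
  if (!all(need %in% names(variance_components)))
    stop("variance_components must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  vc <- variance_components[need]
  if (any(vc < 0)) stop("all variance components must be >= 0", call. = FALSE)
  if (length(group_means) == 1L)
    group_means <- matrix(group_means, 2, 2)
  if (!is.matrix(group_means) || !all(dim(group_means) == c(2, 2)))
    stop("group_means must be a 2 x 2 matrix or a single number",
         call. = FALSE)
  dimnames(group_means) <- list(age_group = c("young", "old"),
                                sex = c("male", "female"))
  structure(list(n_per_group = n_per_group,
                 group_means = group_means,
                 variance_components = vc,
                 n_days = n_days,
                 metric = metric,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a cohort of metric values from a known variance structure
#'
#' Draws metric values under the crossed random-effects model described in
#' [cohort_spec()]. Day and side effects are shared across subjects (they
#' are crossed facets, as in a test-retest design where all subjects attend
#' the same test days), while subject-by-day and subject-by-side
#' interactions and the residual are drawn per observation cell.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return A long `data.frame` with columns `subject`, `age_group`, `sex`,
#'   `test_day`, `side` and the metric column, plus attribute `"spec"`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) stop("a seed is required (in spec or as argument)",
                          call. = FALSE)
  vc <- spec$variance_components
  n <- spec$n_per_group
  cells <- expand.grid(age_group = c("young", "old"),
                       sex = c("male", "female"),
                       stringsAsFactors = FALSE)
  n_subj <- n * nrow(cells)
  sides <- c("left", "right")

  d <- withr::with_seed(seed, {
    subj <- data.frame(
      subject = sprintf("S%03d", seq_len(n_subj)),
      age_group = rep(cells$age_group, each = n),
      sex = rep(cells$sex, each = n),
      stringsAsFactors = FALSE)
    subj$mu <- spec$group_means[cbind(subj$age_group, subj$sex)]
    p <- stats::rnorm(n_subj, sd = sqrt(vc["subject"]))
    day_eff <- stats::rnorm(spec$n_days, sd = sqrt(vc["day"]))
    side_eff <- stats::rnorm(2, sd = sqrt(vc["side"]))
    pd <- matrix(stats::rnorm(n_subj * spec$n_days,
                              sd = sqrt(vc["subject_day"])),
                 n_subj, spec$n_days)
    ps <- matrix(stats::rnorm(n_subj * 2, sd = sqrt(vc["subject_side"])),
                 n_subj, 2)
    out <- expand.grid(subject = seq_len(n_subj),
                       test_day = seq_len(spec$n_days),
                       side = 1:2)
    eps <- stats::rnorm(nrow(out), sd = sqrt(vc["residual"]))
    val <- subj$mu[out$subject] + p[out$subject] +
      day_eff[out$test_day] + side_eff[out$side] +
      pd[cbind(out$subject, out$test_day)] +
      ps[cbind(out$subject, out$side)] + eps
    data.frame(subject = subj$subject[out$subject],
               age_group = subj$age_group[out$subject],
               sex = subj$sex[out$subject],
               test_day = out$test_day,
               side = sides[out$side],
               value = val,
               stringsAsFactors = FALSE)
  })
  names(d)[names(d) == "value"] <- spec$metric
  d <- d[order(d$subject, d$test_day, d$side), ]
  rownames(d) <- NULL
  attr(d, "spec") <- spec
  d
}
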