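---
title: "Median-frequency SEMG fatigue analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-frequency SEMG fatigue analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfsemg)
```

## The measurement problem

During a sustained, high-load isometric contraction (here: a 30-s back
extension at 80% of maximum voluntary contraction), the power spectrum of
the surface electromyogram (SEMG) compresses toward lower frequencies as
metabolic by-products accumulate and muscle-fiber conduction velocity
falls. The median frequency (MF) of the spectrum — the frequency that
splits band-limited power into equal halves — declines approximately
linearly over such a contraction, and the *rate* of that decline is a
non-invasive proxy for the proportion of fast, glycolytic (type II) muscle
fibers that are active. Because aging preferentially removes these fibers,
a *flatter* MF slope in an older individual is a candidate early biomarker
of neuromuscular aging, including in people with chronic low back pain.

`mfsemg` implements this measurement chain for a six-electrode lumbar
montage (left/right at L5 — multifidus, L2 — longissimus, L1 —
iliocostalis lumborum), together with the statistical layers such a study
needs: left/right imbalance indices, trunk-angle quality control,
generalizability-theory (G-theory) test–retest reliability, mixed-effects
age/sex group comparison, and Monte-Carlo power analysis.

## Signal chain

1. **Trim.** The first `trim_start = 3` s of the task (force ramp, posture
   settling) are skipped and analysis ends at `analysis_end = 30` s,
   leaving a 27-s window. Channels carry their own time origin, so
   trimming is idempotent.
2. **Filter.** A 20–500 Hz Butterworth band-pass (order 4) is applied
   forward–backward (`signal::filtfilt`), i.e. zero-phase with an
   effective 8th-order magnitude response. Zero phase matters because
   epoch timing must not shift relative to the mechanical recording.
3. **Artifact scan.** The original protocol "removed artifacts" without
   stating a rule, so the package uses a conservative, reproducible
   stand-in with two parts, applied on the same epoch grid as the spectral
   stage: (a) any sample at ≥ 99% of the ADC full scale (default 11 mV)
   marks its epoch as clipped; (b) epochs whose RMS exceeds 5× the median
   epoch RMS are excluded. Excluded epochs become gaps in the MF series —
   they are never interpolated — and a channel with more than 50% of
   epochs excluded is flagged unusable.
4. **Spectral estimation.** One Blackman-windowed periodogram per 500-ms
   epoch with 50% overlap, power restricted to the 20–500 Hz band, no
   detrending beyond epoch mean removal. The MF of each epoch uses
   mid-bin linear interpolation of the cumulative power, so any spectrum
   symmetric about a frequency has exactly that frequency as its median
   (a flat 20–500 Hz band gives exactly 260 Hz) — this makes the
   estimator's behaviour checkable by closed form.
5. **Output grid.** 500-ms epochs at 50% overlap produce estimates at
   4 Hz, while the protocol's stated output is "27 s of data at 2 Hz, 54
   samples". These are reconciled by averaging adjacent overlapped
   estimates pairwise, emitting the canonical 2 Hz, 54-sample series
   (`mf_output = "paired2hz"`); the raw 4 Hz series remains available
   (`"raw4hz"`). An output point inherits exclusion from either
   constituent epoch. Whether the original analysis instead used 54
   non-overlapping epochs cannot be decided from the protocol wording;
   both interpretations emit 54 points and the choice is a config switch.
6. **Fatigue regression.** Per electrode, ordinary least squares of MF on
   time over non-excluded points (at least 4 required). The intercept is
   evaluated at the *window start* (3 s), since that is where the
   regression domain begins; it is reported as the "onset MF". The
   normalized slope is the exact identity
   `slope_norm = 100 * slope_hz_s / intercept_hz` (%/s). Aggregates:
   `all` (mean over usable electrodes) and `most_negative` (minimum
   normalized slope, ties broken in canonical order L5 left → L1 right).

## Imbalance indices

For each lumbar level the sample-by-sample right/left MF ratio (up to 54
ratios) is mapped through a symmetric transform `R` with `R(1) = 0`,
`R(r) = −R(1/r)`, monotone in `r`, expressed in percent. The exact
transform used in the original literature is not printed; the default is
the percent difference of the larger side relative to the smaller,
`R(r) = 100(r − 1)` for `r ≥ 1` and `−100(1/r − 1)` otherwise, which
satisfies every stated property; `100·log r` is available as an
alternative, and the choice is a config option so downstream code never
depends on it. Averaging the R-series over time gives the signed
*segmental* imbalance (positive = right > left); the *uncompensated*
imbalance is the mean of absolute segmental values and the *compensated*
imbalance the mean of signed values, so `uncompensated ≥ |compensated|`
algebraically, and a left/right swap negates every signed quantity. The
time-mean is taken after the transform (for constant ratios the two orders
agree, which is used as a cross-check in the tests). A point excluded on
either side invalidates that paired ratio sample.

## Trunk-angle quality control

A lever-arm accelerometer (160 Hz, g units) provides the inclination proxy
`angle(t) = asin(acc_z(t))`. Samples marginally outside |1| g (noise,
8-bit quantization at ±1.5 g can overshoot) are clamped with tolerance
0.02; persistent excursions are an error. The onset angle is the mean over
the first second and the drift rate an OLS slope over the trace — the
"position change" computation is not specified in the protocol, and a
regression slope is the natural summary of a near-linear drift. No
smoothing is applied by default so that the noise-free round trip
`asin(sin θ) = θ` is exact to floating-point precision.

## Synthetic data: what it emulates and what it does not

Every stage is validated against a generator with exact ground truth. A
channel is a dense random-phase multisine: 200 cosines whose frequency
offsets are a stratified Gaussian sample (SD `spectral_sd = 10` Hz) around
the programmed trajectory `MF(t) = onset_mf (1 + slope/100 · t)`, all
swept together so the whole spectrum translates with `MF(t)`; equal
amplitudes give a Gaussian-shaped power spectrum that is *symmetric about
MF(t)*, making the programmed trajectory the exact spectral median at
every instant. A white noise floor (0.75 µV RMS, the instrumentation spec)
is added. All draws flow from one seeded local RNG per call; identical
spec and seed give bit-identical signals and the global RNG state is
untouched.

Choices and what they trade away:

* The Gaussian spectral shape with SD 10 Hz is narrower than real SEMG
  spectra (which spread power over well above 100 Hz). The narrow shape
  buys an exact analytic median and epoch-level MF noise (≈ 2.5 Hz SD)
  comparable to what clean high-load recordings show; recovery tolerances
  in the tests are calibrated to this default. Passing tests demonstrate
  correctness of the estimators, not robustness to every spectral shape.
* The generator programs MF(t) from contraction onset (t = 0) while the
  regression reports its intercept at the window start (3 s); for the
  steepest study-range slope (−0.4 %/s) the two differ by ≈ 1.4 Hz at an
  onset of 120 Hz, well inside the ±3 Hz recovery tolerance.
* No motor-unit physiology, force/torque coupling, or nonstationary
  amplitude is simulated.

Cohort-level truth comes from the crossed random-effects model
`y = μ_cell + p + d + s + pd + ps + ε` (subject, day, side facets). The
default variance components for the normalized slope were set so that
single-observation dependability is ≈ 0.92 with an absolute SEM of
≈ 0.044 %/s — the reliability regime typical of multi-day MF-SEMG
protocols — with day-to-day and side-to-side main effects an order of
magnitude below the subject variance. Day and side effects are *shared*
across subjects (crossed facets), as in a design where all subjects attend
the same sessions.

## Reliability (G-theory)

Variance components of the crossed model are estimated by REML
(`lme4::lmer`), which tolerates the mild unbalance of real cohorts;
estimates are bounded at zero and flagged when truncated. For balanced
designs an expected-mean-squares ANOVA solution (`method = "ems"`) is
retained as an exact textbook cross-check (on balanced data the two agree
to numerical precision). The absolute error variance of a protocol
averaging `n_d` days and `n_s` sides is

σ²_abs = σ²_d/n_d + σ²_s/n_s + σ²_pd/n_d + σ²_ps/n_s + σ²_res/(n_d·n_s),

and D = σ²_p / (σ²_p + σ²_abs), SEM = √σ²_abs; the default report is the
single-observation case `n_d = n_s = 1`. The side facet is treated as
error (the quoted measurement model), not as part of the object of
measurement; a bilateral-mean D-study is available by setting
`n_sides = 2`.

**A sampling-theory limitation worth stating plainly:** the `day` and
`side` *main-effect* components carry only `n_days − 1` and 1 degree of
freedom per cohort, so no per-cohort estimate of them can be accurate —
their REML estimator has a sampling SD of order 100% of the true value
however many subjects are enrolled. The validation suite therefore checks
those two components on the *mean across 200 replicate cohorts*
(Monte-Carlo SE ≈ 7–9%), while the subject-indexed components
(subject, subject×day, subject×side, residual — hundreds of df) are
checked on a single 500-subject cohort. Replicate sizes were fixed from
this degrees-of-freedom arithmetic.

## Group statistics and power

The inferential model per outcome is a linear mixed model with fixed age
group, sex, their interaction and test day (a 3-level factor), and a
random intercept per person; Type III F tests with Satterthwaite
denominator df (`lmerTest`). Main comparisons are Bonferroni-adjusted for
the family of 5 outcomes (significance at raw p ≤ 0.01). When a main
effect or interaction is of interest, estimated-marginal-mean contrasts of
age within sex and sex within age are Holm-adjusted. Cohen's d for a
contrast is the EMM difference divided by the model-implied
between-subject SD √(σ²_subject + σ²_residual); for plain two-sample
calls, `cohens_d()` uses the pooled-SD definition. With a single test day
the model reduces to OLS on the same fixed effects. Test day is entered as
a factor (it is a design label, not a dose).

`power_simulation()` simulates at the analysis unit — one bilateral-mean
value per subject and day, with persistent subject effect and day-level
error — applies standardized effects to the cell means, runs the full
model-plus-threshold chain, and scans a sample-size grid; the returned
requirement is inflated by `1/(1 − attrition)` for expected signal loss
(default 10%). Effect sizes are inputs, not constants baked in. With one
day and no residual the age comparison collapses to a textbook two-sample
design, which the tests use as an analytic oracle
(`stats::power.t.test`). Under null effects the chain's rejection rate at
the corrected per-comparison level 0.01 is itself verified at ≈ 0.01 over
1000 simulated cohorts.

## Numerical conventions

* MF interpolation: mid-bin cumulative interpolation (exact for symmetric
  spectra, both bin parities).
* Epoch alignment: first epoch starts exactly at the trim point; a
  trailing partial epoch is discarded; the unpaired 107th epoch stands
  alone in the last 2 Hz output sample.
* Ties for the most negative electrode break in canonical order (L5
  before L2 before L1, left before right).
* Recordings shorter than the analysis window are a hard error unless
  `allow_short = TRUE`, which analyses the available span with a warning.
* Recording files store doubles at full round-trip precision in
  tab-separated text with a `key: value` metadata sidecar; times are
  seconds from contraction onset everywhere (never sample indices).
* Validation problem sizes: spectral-recovery checks use 20 seeds per
  programmed (onset, slope) cell over a 3×3 grid; calibration checks use
  1000 simulated cohorts of 80 subjects; power checks 200 cohorts of 200
  subjects; reliability recovery one 500-subject cohort plus 200
  replicates of 40 subjects.

## Known limitations

* The artifact rule and the symmetric-ratio transform are documented
  stand-ins for unspecified steps of the original protocol; both are
  config-pluggable.
* MF series from overlapping epochs are serially correlated; the OLS
  fatigue fit ignores this (as the original analysis did), which affects
  the r² and any naive slope SE, not the slope estimate itself.
* The generator's spectral realism is deliberately limited (see above);
  conclusions about estimator performance on pathological real-world
  signals (powerline interference, ECG crosstalk, electrode lift-off
  beyond the clip/RMS rules) are out of scope, as is notch filtering.
* Reported cohort values from the motivating study are not reproducible
  here because its recordings were never deposited; validation rests on
  synthetic ground truth and closed forms instead.

## A worked example

```{r, eval = FALSE}
library(mfsemg)

# one synthetic recording with known truth
specs <- lapply(semg_labels(), function(lab) {
  lv <- sub("_.*$", "", lab)
  channel_spec(lab, onset_mf = c(L5 = 118, L2 = 100, L1 = 86)[[lv]],
               normalized_slope = -0.2)
})
rec <- generate_recording(specs, angle = angle_profile(25.39, 0.07),
                          seed = 11)
a <- analyze_recording(rec)
print(a$fatigue)
print(a$imbalance)
print(a$kinematics)

# a small end-to-end cohort run
res <- run_pipeline(out_dir = tempfile(),
                    simulate = list(n_per_group = 2, n_days = 2),
                    seed = 1)
print(res)
```
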