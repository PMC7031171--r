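# mfsemg

Median-frequency surface-EMG (MF-SEMG) fatigue analysis of the lumbar back
extensors, for researchers who assess back-muscle capability from sustained
isometric contractions (e.g. a 30-s hold at 80% of maximum voluntary
contraction) with a bilateral six-electrode montage (L5 — multifidus,
L2 — longissimus, L1 — iliocostalis lumborum) plus a lever-arm
accelerometer.

As a fatiguing muscle accumulates metabolic by-products, its SEMG power
spectrum compresses toward lower frequencies. The package estimates the
spectral median frequency MF per 500-ms Blackman-windowed epoch (50%
overlap, emitted as a 2 Hz, 54-sample series over the 27-s analysis
window) and fits, per electrode,

    MF(t) = MF0 + b · t,        slope_norm = 100 · b / MF0   [%/s]

where `MF0` (the regression intercept at the window start, "onset MF")
indexes initial spectral content and the normalized slope `slope_norm` is
the fatigue rate — more negative means faster spectral compression, i.e.
a larger share of active fast glycolytic fibers. Around this core the
package provides:

* preprocessing: 3-s onset trim, zero-phase 20–500 Hz Butterworth
  band-pass, epoch-level artifact rejection (clip and RMS-outlier rules);
* aggregates: per-recording mean over electrodes and the *most negative*
  electrode;
* left/right imbalance: symmetric corrected ratio R per lumbar level
  (R(1) = 0, R(r) = −R(1/r)), with global *uncompensated* (mean |R|) and
  *compensated* (mean R) indices;
* trunk-angle quality control from the accelerometer
  (`angle = asin(acc_z)`): onset angle and drift rate;
* G-theory test–retest reliability: REML variance components over
  subject/day/side facets, dependability coefficient
  `D = σ²_p / (σ²_p + σ²_abs)` and absolute SEM `√σ²_abs`;
* mixed-effects age/sex group comparison (random person intercept,
  Type III Satterthwaite F, Bonferroni family of 5, Holm-adjusted EMM
  post hocs, Cohen's d) and a Monte-Carlo power simulation for study
  planning;
* a synthetic-signal generator whose programmed MF trajectory is the
  *exact* spectral median at every instant, so every stage can be
  validated against known ground truth.

## Worked example

```r
library(mfsemg)

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
```

```
MF fatigue summary
  L5_left   onset  117.47 Hz  slope  -0.2205 %/s
  L5_right  onset  116.78 Hz  slope  -0.1562 %/s
  L2_left   onset   99.22 Hz  slope  -0.2113 %/s
  L2_right  onset   99.62 Hz  slope  -0.2239 %/s
  L1_left   onset   85.01 Hz  slope  -0.1862 %/s
  L1_right  onset   85.83 Hz  slope  -0.1981 %/s
  all (n=6): onset 100.65 Hz, slope -0.1994 %/s
  most negative: L2_right (-0.2239 %/s)
Left/right MF imbalance (positive = right > left)
  L5: +0.33 %
  L2: +0.23 %
  L1: +0.84 %
  uncompensated: 0.47 %   compensated: +0.47 %
Trunk angle: onset 25.50 deg, drift 0.0710 deg/s (4800 samples, 0 clamped)
```

The six onsets and normalized slopes recover the programmed values
(onsets 118/100/86 Hz, slope −0.2 %/s) within the estimator's noise; a
symmetric montage yields imbalance near zero; and the accelerometer
analysis recovers the programmed 25.39° onset inclination and
0.07 deg/s drift.

Reliability of a protocol, from its variance components:

```r
dependability(c(subject = 0.0233, day = 1e-4, side = 1e-4,
                subject_day = 9e-4, subject_side = 4e-4,
                residual = 4.4e-4))
#> Dependability (n_days = 1, n_sides = 1)
#>   D = 0.923, absolute SEM = 0.044
```

An end-to-end cohort run (simulate → per-recording metrics → reliability
→ group statistics, with CSV outputs and a run manifest):

```r
res <- run_pipeline(out_dir = "out",
                    simulate = list(n_per_group = 2, n_days = 2),
                    seed = 1)
```

See the methods vignette (`vignettes/mf-semg-fatigue.Rmd`) for the model,
its assumptions, parameter defaults, and design decisions.

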