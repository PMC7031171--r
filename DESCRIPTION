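Package: mfsemg
Title: Median-Frequency Surface EMG Fatigue Analysis of the Back Extensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing muscle fatigue of the lumbar back extensors
    from multi-channel surface electromyography (SEMG) recorded during
    sustained isometric contractions. Implements the median-frequency (MF)
    fatigue method end to end: band-pass preprocessing with artifact
    rejection, short-time Blackman-window spectral estimation of the MF time
    series, per-electrode linear fatigue regressions (Hz/s and normalized
    %/s slopes), left/right symmetric-ratio imbalance indices, trunk-angle
    quality control from a lever-arm accelerometer, generalizability-theory
    test-retest reliability (dependability coefficient and absolute SEM),
    linear mixed-effects age/sex group comparisons with estimated marginal
    mean post hocs, and Monte Carlo power simulation for study planning. A
    synthetic-signal generator with exactly known spectral ground truth
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
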