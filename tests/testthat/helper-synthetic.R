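# Shared fixtures, all built in code.

# An mf_series object with programmed values on the default 2 Hz grid.
make_series <- function(mf, electrode = "L5_left", window_start = 3,
                        rate = 2, excluded = rep(FALSE, length(mf))) {
  structure(list(electrode = electrode,
                 times = window_start + (seq_along(mf) - 1) / rate + 0.375,
                 mf = ifelse(excluded, NA_real_, mf),
                 excluded = excluded,
                 output_rate = rate,
                 window_start = window_start,
                 usable = sum(!excluded) >= 4),
            class = "mf_series")
}

# Run one generated channel through the default pipeline.
recover_fit <- function(onset, slope, seed, config = semg_config()) {
  sp <- channel_spec("L5_left", onset_mf = onset, normalized_slope = slope)
  x <- generate_semg_channel(sp, duration = config$analysis_end,
                             fs = config$semg_fs, seed = seed)
  fatigue_fit(mf_series(preprocess_channel(x, config), config))
}

# Six-channel spec set with optional right/left onset asymmetry.
default_specs <- function(slope = -0.2, ratio = 1,
                          onset = c(L5 = 118, L2 = 100, L1 = 86)) {
  lapply(semg_labels(), function(lab) {
    lv <- sub("_.*$", "", lab)
    fac <- if (grepl("right$", lab)) sqrt(ratio) else 1 / sqrt(ratio)
    channel_spec(lab, onset_mf = onset[[lv]] * fac,
                 normalized_slope = slope)
  })
}
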