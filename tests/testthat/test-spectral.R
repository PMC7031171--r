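test_that("median frequency of symmetric spectra is the centre of symmetry", {
  f <- seq(20, 500, by = 2)
  expect_equal(median_frequency(f, rep(1, length(f))), 260, tolerance = 1e-12)
  # even number of bins: interpolation must still land on the centre
  f2 <- seq(20, 498, by = 2)
  expect_equal(median_frequency(f2, rep(1, length(f2))), 259,
               tolerance = 1e-12)
  # all mass in one bin
  p <- rep(0, length(f)); p[f == 250] <- 3.7
  expect_equal(median_frequency(f, p), 250)
  # band restriction applies before the median
  expect_equal(median_frequency(f, rep(1, length(f)), band = c(100, 300)),
               200, tolerance = 1e-12)
})

test_that("median frequency rejects degenerate spectra", {
  f <- seq(20, 500, by = 2)
  expect_error(median_frequency(f, rep(0, length(f))), "zero total power")
  expect_error(median_frequency(f, c(-1, rep(1, length(f) - 1))),
               "non-negative")
})

test_that("pure-tone periodogram has its median at the tone", {
  fs <- 2000
  t <- (0:(fs * 30 - 1)) / fs
  x <- semg_channel(1e-4 * sin(2 * pi * 100 * t), fs = fs, t0 = 0,
                    label = "L5_left")
  s <- mf_series(preprocess_channel(x))
  expect_true(all(abs(s$mf - 100) <= 2))
  # independent oracle: direct cumulative sum on one hand-built periodogram
  seg <- as.numeric(x)[6001:7000]
  n <- length(seg)
  w <- 0.42 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)) +
    0.08 * cos(4 * pi * (0:(n - 1)) / (n - 1))
  spec <- Mod(fft((seg - mean(seg)) * w)[1:(n / 2 + 1)])^2
  freqs <- (0:(n / 2)) * fs / n
  keep <- freqs >= 20 & freqs <= 500
  cs <- cumsum(spec[keep])
  oracle <- freqs[keep][which(cs >= cs[length(cs)] / 2)[1]]
  expect_lt(abs(oracle - 100), 2.1)
  expect_lt(abs(median_frequency(freqs, spec, c(20, 500)) - oracle), 2.1)
})

test_that("default epoching yields 54 points spanning the 27-s window", {
  x <- generate_semg_channel(channel_spec("L2_left"), 30, 2000, seed = 3)
  s <- mf_series(preprocess_channel(x))
  expect_length(s$mf, 54)
  expect_equal(s$output_rate, 2)
  expect_true(all(diff(s$times) == 0.5))
  expect_true(min(s$times) >= 3 && max(s$times) < 30)
  expect_true(all(s$mf >= 20 & s$mf <= 500))
  # raw mode exposes the 4 Hz epoch series the 2 Hz output is built from
  s4 <- mf_series(preprocess_channel(x),
                  semg_config(mf_output = "raw4hz"))
  expect_length(s4$mf, 107)
  expect_equal(s4$output_rate, 4)
})

test_that("MF series is invariant to positive rescaling of the channel", {
  x <- generate_semg_channel(channel_spec("L1_right"), 30, 2000, seed = 4)
  base <- bandpass_filter(trim_window(x))
  s1 <- mf_series(base)
  for (fac in c(1 / 137.5, 3)) {
    y <- semg_channel(as.numeric(base) * fac, fs = 2000, t0 = 3,
                      label = "L1_right")
    s2 <- mf_series(y)
    expect_lt(max(abs(s1$mf - s2$mf)), 1e-9)
  }
})

test_that("excluded epochs propagate as excluded output points", {
  x <- generate_semg_channel(channel_spec("L5_left"), 30, 2000, seed = 5)
  scan <- preprocess_channel(x)
  mask <- scan$excluded
  mask[c(11, 30)] <- TRUE  # raw epochs in distinct output pairs
  s <- mf_series(scan$x, exclude = mask)
  expect_length(s$mf, 54)
  expect_equal(sum(s$excluded), 2)
  expect_equal(which(s$excluded), c(6, 15))
  expect_true(all(is.na(s$mf[s$excluded])))
})

test_that("epoch longer than the signal is rejected", {
  x <- semg_channel(rnorm(800), fs = 2000, t0 = 3)
  expect_error(mf_series(x), "epoch longer")
})

test_that("time reversal of a stationary channel preserves the MF distribution", {
  x <- generate_semg_channel(channel_spec("L5_left", normalized_slope = 0),
                             30, 2000, seed = 6)
  fwd <- mf_series(preprocess_channel(x))
  rev_ch <- semg_channel(rev(as.numeric(x)), fs = 2000, t0 = 0,
                         label = "L5_left")
  bwd <- mf_series(preprocess_channel(rev_ch))
  expect_gt(suppressWarnings(ks.test(fwd$mf, bwd$mf)$p.value), 0.01)
})

test_that("fitted slopes track programmed slopes monotonically", {
  slopes <- c(0, -0.2, -0.4)
  fitted <- vapply(seq_along(slopes), function(i)
    recover_fit(100, slopes[i], seed = 100 + i)$slope_norm, numeric(1))
  expect_true(all(diff(fitted) < 0))
})
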