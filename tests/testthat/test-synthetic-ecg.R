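test_that("NSR generation produces one dominant R peak per beat", {
  spec <- rhythm_spec("NSR", fs = 250, duration = 8, heart_rate = 60,
                      seed = 1)
  x <- gen_rhythm(spec)
  expect_length(x, 2000)
  ## count local maxima above 0.5 mV
  peaks <- sum(diff(sign(diff(x))) == -2 & x[2:(length(x) - 1)] > 0.5)
  expect_gte(peaks, 7)
  expect_lte(peaks, 9)
})

test_that("NSR autocorrelation peaks near the RR interval", {
  for (hr in c(60, 90)) {
    x <- gen_rhythm(rhythm_spec("NSR", fs = 250, duration = 16,
                                heart_rate = hr, seed = 5))
    ac <- stats::acf(x, lag.max = 400, plot = FALSE)$acf[-1]
    lag_peak <- which.max(ac[50:400]) + 49
    expect_lt(abs(lag_peak / 250 - 60 / hr), 0.1 * 60 / hr)
  }
})

test_that("VF spectral centroid stays in the dominant band", {
  x <- gen_rhythm(rhythm_spec("VF", fs = 250, duration = 8, seed = 7))
  expect_length(x, 2000)
  cen <- spectral_centroid(x, 250)
  expect_gte(cen, 3)
  expect_lte(cen, 8)
})

test_that("VF keeps >= 90% of power inside 2-10 Hz across seeds", {
  for (s in 1:8) {
    x <- gen_rhythm(rhythm_spec("VF", fs = 250, duration = 8, seed = s))
    expect_gte(band_power_fraction(x, 250, 2, 10), 0.90)
    ## no flat baseline: no 0.2 s run with negligible excursion
    seg <- matrix(x[1:1950], nrow = 50)
    expect_gt(min(apply(seg, 2, function(v) diff(range(v)))), 1e-3)
  }
})

test_that("VT is a fast periodic oscillation at the requested rate", {
  x <- gen_rhythm(rhythm_spec("VT", fs = 250, duration = 8,
                              heart_rate = 200, seed = 3))
  cen <- spectral_centroid(x, 250)
  ## fundamental 3.33 Hz with harmonics 6.7/10 Hz pulls the centroid up
  expect_gt(cen, 3)
  expect_lt(cen, 12)
  ## dominant periodogram line at the fundamental
  X <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * 250 / length(x)
  expect_lt(abs(f[which.max(X[1:1000])] - 200 / 60), 0.3)
})

test_that("generation is a pure function of the spec including the seed", {
  for (cls in c("NSR", "VT", "VF")) {
    a <- gen_rhythm(rhythm_spec(cls, seed = 3))
    b <- gen_rhythm(rhythm_spec(cls, seed = 3))
    c <- gen_rhythm(rhythm_spec(cls, seed = 4))
    expect_identical(a, b)
    expect_true(any(a != c))
  }
})

test_that("invalid rhythm specs are rejected", {
  expect_error(rhythm_spec("NSR", duration = -1), class = "tfarr_invalid_spec")
  expect_error(rhythm_spec("NSR", fs = 0), class = "tfarr_invalid_spec")
  expect_error(rhythm_spec("VF", fs = 10), class = "tfarr_invalid_spec")
  expect_error(rhythm_spec("VT", heart_rate = -10),
               class = "tfarr_invalid_spec")
})

test_that("add_noise hits the requested SNR and respects its contract", {
  x <- gen_rhythm(rhythm_spec("VF", fs = 250, duration = 60, seed = 2))
  expect_identical(add_noise(x, 250, NULL), x)
  expect_identical(add_noise(x, 250, Inf), x)
  y <- add_noise(x, 250, snr_db = 0, seed = 9)
  snr <- 10 * log10(mean(x^2) / mean((y - x)^2))
  expect_lt(abs(snr), 0.1)
  ## measured noise power within 2% of signal power at 0 dB
  expect_lt(abs(mean((y - x)^2) / mean(x^2) - 1), 0.02)
  expect_identical(add_noise(x, 250, 10, seed = 4),
                   add_noise(x, 250, 10, seed = 4))
  expect_error(add_noise(numeric(100), 250, 10),
               class = "tfarr_invalid_input")
})

test_that("gen_dataset returns the right frame geometry and is seeded", {
  ds <- gen_dataset(10, classes = c("NSR", "VF"), frame_s = 4, fs = 250,
                    seed = 1)
  expect_equal(nrow(ds), 20)
  expect_true(all(lengths(ds$signal) == 1000))
  expect_equal(as.integer(table(ds$rhythm)), c(10, 10))
  ds8 <- gen_dataset(2, classes = "VF", frame_s = 8, fs = 250, seed = 1)
  expect_true(all(lengths(ds8$signal) == 2000))
  expect_identical(gen_dataset(3, c("NSR", "VF"), seed = 11),
                   gen_dataset(3, c("NSR", "VF"), seed = 11))
  expect_error(gen_dataset(3, character(0)), class = "tfarr_invalid_spec")
})
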