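test_that("mid-passband sinusoids pass essentially unattenuated", {
  tr <- sine_trial(15, fs = 250, duration = 5)
  out <- bandpass_zero_phase(tr, band_spec(8, 30))
  amp_at <- function(x, f, fs) {
    n <- length(x)
    2 * Mod(stats::fft(x))[round(f * n / fs) + 1L] / n
  }
  ratio <- amp_at(out$data[1, ], 15, 250) / amp_at(tr$data[1, ], 15, 250)
  expect_lt(abs(ratio - 1), 0.02)
})

test_that("stop-band sinusoids are strongly attenuated", {
  tr <- sine_trial(2, fs = 250, duration = 5)
  out <- bandpass_zero_phase(tr, band_spec(8, 30))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out$data[1, ]) / rms(tr$data[1, ]), 0.10)
})

test_that("the two-pass filter introduces no net phase shift", {
  tr <- sine_trial(10, fs = 125, duration = 5)
  out <- bandpass_zero_phase(tr, band_spec(8, 30))
  cc <- stats::ccf(tr$data[1, ], out$data[1, ], lag.max = 10, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
})

test_that("filtering is linear and leaves rows centred", {
  set.seed(42)
  X1 <- matrix(stats::rnorm(3 * 500), 3)
  X2 <- matrix(stats::rnorm(3 * 500), 3)
  mk <- function(X) ssvep_trial(X, 125, 1L, 1L, 10)
  band <- band_spec(8, 30)
  f1 <- bandpass_zero_phase(mk(X1), band)$data
  f2 <- bandpass_zero_phase(mk(X2), band)$data
  f12 <- bandpass_zero_phase(mk(3 * X1 + X2), band)$data
  expect_equal(f12, 3 * f1 + f2, tolerance = 1e-9)
  expect_true(all(abs(rowMeans(f12)) < 1e-6 * apply(f12, 1, stats::sd)))
})

test_that("stop-band energy of filtered broadband noise is under 1%", {
  set.seed(7)
  tr <- ssvep_trial(matrix(stats::rnorm(1250), 1), 250, 1L, 1L, 10)
  out <- bandpass_zero_phase(tr, band_spec(8, 30))$data[1, ]
  n <- length(out)
  # Hann-windowed periodogram: a rectangular window's sidelobes would smear
  # passband energy into the stop bands and mask the filter's attenuation
  h <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  spec <- Mod(stats::fft(out * h))[seq_len(n / 2)]^2
  freqs <- (seq_len(n / 2) - 1) * 250 / n
  stop_e <- sum(spec[freqs < 6 | freqs > 35])
  expect_lt(stop_e / sum(spec), 0.01)
})

test_that("band edges above Nyquist and too-short trials are rejected", {
  tr <- sine_trial(10, fs = 50, duration = 2)
  expect_error(bandpass_zero_phase(tr, band_spec(8, 30)), "Nyquist")
  short <- ssvep_trial(matrix(stats::rnorm(10), 1), 250, 1L, 1L, 10)
  expect_error(bandpass_zero_phase(short, band_spec(8, 30)), "short")
})

test_that("filterbank expansion preserves order, shape and band selectivity", {
  tr <- sine_trial(10, fs = 250, duration = 3)
  one <- filter_bank(band_spec(8, 30))
  expect_equal(apply_filterbank(tr, one)[[1]]$data,
               bandpass_zero_phase(tr, band_spec(8, 30))$data)

  set.seed(1)
  multi <- ssvep_trial(matrix(stats::rnorm(9 * 750), 9), 250, 1L, 1L, 10)
  bank4 <- default_filterbank(8, 30, 4)
  out <- apply_filterbank(multi, bank4)
  expect_length(out, 4L)
  for (o in out) expect_identical(dim(o$data), c(9L, 750L))

  sel <- filter_bank(list(band_spec(8, 13), band_spec(20, 30)))
  parts <- apply_filterbank(tr, sel)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(parts[[1]]$data), 5 * rms(parts[[2]]$data))
})

test_that("windowing keeps the requested sample range", {
  tr <- sine_trial(10, fs = 250, duration = 5)
  expect_identical(ncol(window_trial(tr, window_spec(0.5))$data), 125L)
  expect_identical(window_trial(tr, window_spec(5))$data, tr$data)
  w <- window_trial(tr, window_spec(1, onset_offset_s = 2))
  expect_identical(w$data[1, ], tr$data[1, 501:750])
  expect_error(window_trial(tr, window_spec(2.5, onset_offset_s = 3)), "beyond")
  expect_identical(w$subject_id, tr$subject_id)
})

test_that("channel selection subsets and reorders rows", {
  X <- matrix(seq_len(18), 3, dimnames = list(c("Oz", "O1", "O2"), NULL))
  tr <- ssvep_trial(X, 250, 1L, 1L, 10, channel_names = rownames(X))
  expect_identical(select_channels(tr, c("Oz", "O1", "O2"))$data, tr$data)
  one <- select_channels(tr, "O2")
  expect_identical(dim(one$data), c(1L, 6L))
  expect_identical(one$data[1, ], tr$data[3, ])
  rev2 <- select_channels(tr, c("O1", "Oz"))
  expect_identical(rev2$channel_names, c("O1", "Oz"))
  expect_error(select_channels(tr, "XX"), "unknown channel")
})
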