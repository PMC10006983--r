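test_that("subject models are deterministic in the seed and unit-normalized", {
  a <- make_subject(1L, 9L, 2L, 5.0)
  b <- make_subject(1L, 9L, 2L, 5.0)
  expect_identical(a, b)

  c <- make_subject(2L, 9L, 2L, 5.0)
  expect_gt(max(abs(a$mixing_matrix - c$mixing_matrix)), 0)

  d <- make_subject(7L, 4L, 2L, 0.0)
  expect_equal(colSums(d$mixing_matrix^2), rep(1, 2), tolerance = 1e-12)

  expect_error(make_subject(1L, 2L, 3L, 0), "exceed")
  expect_error(make_subject(1L, 4L, 2L, 0, harmonic_amplitudes = c(0, 0, 0)),
               "not all zero")
})

test_that("noiseless trials peak at the stimulation frequency on driven channels", {
  cfg <- sim_config(n_subjects = 1L, stim_frequencies_hz = 10, fs_hz = 250,
                    trial_duration_s = 2, n_channels = 6L, snr_db = Inf,
                    seed = 3L)
  subj <- make_subject(3L, 6L, 2L, Inf)
  tr <- simulate_trial(subj, 10, cfg, seed = 1L)
  # per-channel response amplitude: coherent sum of the quadrature sources
  drive <- abs(subj$mixing_matrix %*% exp(1i * (seq_len(2) - 1) * pi / 2))
  nt <- ncol(tr$data)
  half <- seq_len(floor(nt / 2))
  stim_bin <- round(10 * nt / cfg$fs_hz) + 1L
  for (ch in which(Mod(drive) > 0.05)) {
    spec <- Mod(stats::fft(tr$data[ch, ]))[half]
    expect_equal(which.max(spec), stim_bin)
  }
})

test_that("silent sources give white noise with near-zero periodic autocorrelation", {
  cfg <- sim_config(n_subjects = 1L, stim_frequencies_hz = 10, fs_hz = 250,
                    trial_duration_s = 4, n_channels = 4L, snr_db = 5,
                    noise_model = "white", seed = 9L)
  subj <- make_subject(9L, 4L, 2L, 5)
  subj$harmonic_amplitudes <- c(0, 0, 0)     # hand-built silent source model
  tr <- simulate_trial(subj, 10, cfg, seed = 21L)
  lag <- cfg$fs_hz / 10
  nt <- ncol(tr$data)
  for (ch in seq_len(4)) {
    x <- tr$data[ch, ]
    r <- stats::cor(x[seq_len(nt - lag)], x[seq_len(nt - lag) + lag])
    expect_lt(abs(r), 3 / sqrt(nt))
  }
})

test_that("trial simulation is deterministic for a fixed noise seed", {
  cfg <- small_config()
  subj <- make_subject(4L, cfg$n_channels, 2L, 10)
  t1 <- simulate_trial(subj, 10, cfg, seed = 5L)
  t2 <- simulate_trial(subj, 10, cfg, seed = 5L)
  expect_identical(t1$data, t2$data)
  t3 <- simulate_trial(subj, 10, cfg, seed = 6L)
  expect_gt(max(abs(t1$data - t3$data)), 0)
})

test_that("a dataset has one trial per (subject, block, frequency) cell", {
  cfg <- sim_config(n_subjects = 10L, n_blocks = 6L, stim_frequencies_hz = 10,
                    fs_hz = 250, trial_duration_s = 1, seed = 2L)
  ts <- simulate_dataset(cfg)
  expect_length(ts$trials, 60L)
  sid <- vapply(ts$trials, `[[`, integer(1), "subject_id")
  expect_true(all(table(sid) == 6L))
  blk <- vapply(ts$trials, `[[`, integer(1), "block_index")
  expect_true(all(table(sid, blk) == 1L))
})

test_that("the dataset is a pure function of its configuration", {
  a <- simulate_dataset(small_config())
  b <- simulate_dataset(small_config())
  expect_identical(a, b)
})

test_that("realized channel SNR matches the requested level within 1 dB", {
  for (snr in c(-5, 0, 10)) {
    cfg <- small_config(snr_db = snr)
    subj <- make_subject(8L, cfg$n_channels, 2L, snr)
    noisy <- simulate_trial(subj, 10, cfg, seed = 31L)
    subj_clean <- subj; subj_clean$snr_db <- Inf
    clean <- simulate_trial(subj_clean, 10, cfg, seed = 31L)
    noise <- noisy$data - clean$data
    realized <- 10 * log10(mean(clean$data^2) / mean(noise^2))
    expect_lt(abs(realized - snr), 1)
  }
})

test_that("mixing-matrix separation shrinks monotonically as the knob rises", {
  mean_angle <- function(sep) {
    cfg <- small_config(subject_separation = sep)
    subs <- ssvepid:::build_subject_models(cfg)
    pairs <- utils::combn(length(subs), 2)
    mean(apply(pairs, 2, function(ij) {
      q1 <- qr.Q(qr(subs[[ij[1]]]$mixing_matrix))
      q2 <- qr.Q(qr(subs[[ij[2]]]$mixing_matrix))
      s <- svd(crossprod(q1, q2))$d
      mean(acos(pmin(1, s)))          # principal angles
    }))
  }
  angles <- vapply(c(0, 0.5, 0.9, 1), mean_angle, numeric(1))
  expect_true(all(diff(angles) < 0))
  expect_lt(angles[4], 1e-6)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_blocks = 1L), "blocks")
  expect_error(sim_config(fs_hz = 50, stim_frequencies_hz = 10), "harmonic")
  expect_error(sim_config(stim_frequencies_hz = c(10, -2)), "positive")
  expect_error(sim_config(subject_separation = 1.5), "separation")
})
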