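# Shared fixtures, built in code and cached across test files.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Small but non-trivial design: 4 subjects x 3 blocks, 6 channels, 2 s trials.
small_config <- function(...) {
  defaults <- list(n_subjects = 4L, n_blocks = 3L, stim_frequencies_hz = 10,
                   fs_hz = 125, trial_duration_s = 2, n_channels = 6L,
                   snr_db = 10, subject_separation = 0, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_set <- function() cached("small_set", simulate_dataset(small_config()))

# Two analysis bands keep unit tests quick; p = 2 filters per spectrum end.
small_bank <- function() default_filterbank(8, 30, n_bands = 2L)

# Random SPD matrix with unit trace (a plausible class covariance).
rand_spd <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  C <- crossprod(A) + 0.05 * diag(n)
  C / sum(diag(C))
}

# A pure-sinusoid single-channel trial.
sine_trial <- function(freq, fs = 250, duration = 5, amp = 1) {
  tt <- (seq_len(round(fs * duration)) - 1) / fs
  ssvep_trial(matrix(amp * sin(2 * pi * freq * tt), 1), fs, 1L, 1L, freq)
}

# Fast DFN configuration for unit tests (full settings are exercised in the
# acceptance suite).
quick_dfn <- function(...) {
  do.call(dfn_config, utils::modifyList(list(epochs = 60L), list(...)))
}
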