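#' Simulation configuration for synthetic SSVEP data
#'
#' Describes a complete synthetic study: how many subjects and blocks, which
#' stimulation frequencies, the recording geometry, and how hard the
#' identification problem is. Subject identity is carried by a
#' subject-specific spatial mixing matrix: each subject's cortical sources
#' project onto the channels through their own channel-weight pattern, which
#' is the premise of spatial-filter-based person identification.
#'
#' `subject_separation` interpolates between fully individual mixing matrices
#' (0) and one matrix shared by everyone (1); at 1 the trials carry no
#' identity information and any classifier must fall to chance.
#'
#' @param n_subjects,n_blocks Design size (blocks are repetition sweeps; at
#'   least 2 blocks so leave-one-block-out evaluation is possible).
#' @param stim_frequencies_hz Stimulation frequencies (Hz).
#' @param fs_hz Sampling rate (Hz); must exceed twice the highest modelled
#'   harmonic.
#' @param trial_duration_s Trial length in seconds.
#' @param n_channels,n_sources Channel count and number of cortical sources.
#' @param snr_db Source-to-noise power ratio in dB (`Inf` = noiseless).
#' @param noise_model `"white"` or `"white_plus_pink"` (equal power split;
#'   the 1/f component mimics the broadband EEG background).
#' @param subject_separation In `[0, 1]`; similarity of mixing matrices
#'   across subjects (1 = identical).
#' @param harmonic_amplitudes Amplitudes of the stimulation-frequency
#'   harmonics; the default (1, 0.5, 0.25) mimics the typical SSVEP
#'   harmonic roll-off.
#' @param seed Integer master seed; the whole data set is a pure function of
#'   this configuration.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10L, n_blocks = 6L,
                       stim_frequencies_hz = 10, fs_hz = 250,
                       trial_duration_s = 5, n_channels = 9L,
                       n_sources = 2L, snr_db = 10,
                       noise_model = c("white_plus_pink", "white"),
                       subject_separation = 0,
                       harmonic_amplitudes = c(1, 0.5, 0.25),
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  H <- length(harmonic_amplitudes)
  if (n_blocks < 2L) stop("need at least 2 blocks", call. = FALSE)
  if (any(stim_frequencies_hz <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (fs_hz <= 2 * max(stim_frequencies_hz) * H)
    stop("fs_hz must exceed twice the highest modelled harmonic", call. = FALSE)
  if (subject_separation < 0 || subject_separation > 1)
    stop("subject_separation must lie in [0, 1]", call. = FALSE)
  if (n_sources < 1L || n_sources > n_channels)
    stop("need 1 <= n_sources <= n_channels", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), n_blocks = as.integer(n_blocks),
         stim_frequencies_hz = as.numeric(stim_frequencies_hz),
         fs_hz = as.numeric(fs_hz), trial_duration_s = as.numeric(trial_duration_s),
         n_channels = as.integer(n_channels), n_sources = as.integer(n_sources),
         snr_db = as.numeric(snr_db), noise_model = noise_model,
         subject_separation = as.numeric(subject_separation),
         harmonic_amplitudes = as.numeric(harmonic_amplitudes),
         seed = as.integer(seed)),
    class = "sim_config")
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-(subject, block, frequency) stream seed below 2^31.
stream_seed <- function(seed, s, b = 0L, f = 0L) {
  as.integer((as.double(seed) * 1000003 + s * 10007 + b * 101 + f) %% 2147483629)
}

#' Build a synthetic subject model
#'
#' Draws a subject-specific spatial mixing matrix (standard-normal entries,
#' columns normalized to unit Euclidean norm) together with the harmonic
#' amplitude/phase profile of that subject's SSVEP response. Deterministic
#' for a fixed seed.
#'
#' @param seed Integer seed for this subject.
#' @param n_channels,n_sources Geometry; `n_sources <= n_channels`.
#' @param snr_db Source-to-noise ratio the simulator will realize.
#' @param harmonic_amplitudes Non-negative harmonic amplitudes (length H).
#' @param subject_id Identity label carried into the generated trials.
#'
#' @return A list of class `subject_model` with fields `mixing_matrix`
#'   (`n_channels x n_sources`, unit columns), `harmonic_amplitudes`,
#'   `harmonic_phases` (radians), `snr_db`, `subject_id`.
#' @export
make_subject <- function(seed, n_channels, n_sources, snr_db,
                         harmonic_amplitudes = c(1, 0.5, 0.25),
                         subject_id = 1L) {
  if (n_sources > n_channels)
    stop("n_sources may not exceed n_channels", call. = FALSE)
  if (n_sources < 1L) stop("need at least one source", call. = FALSE)
  if (any(harmonic_amplitudes < 0) || all(harmonic_amplitudes == 0))
    stop("harmonic amplitudes must be non-negative and not all zero", call. = FALSE)
  with_seed(seed, {
    A <- matrix(stats::rnorm(n_channels * n_sources), n_channels, n_sources)
    A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
    phases <- stats::runif(length(harmonic_amplitudes), 0, 2 * pi)
    structure(
      list(subject_id = as.integer(subject_id), mixing_matrix = A,
           harmonic_amplitudes = as.numeric(harmonic_amplitudes),
           harmonic_phases = phases, snr_db = as.numeric(snr_db)),
      class = "subject_model")
  })
}

# Spherical interpolation of unit columns of `from` toward matching columns of
# `to`; t = 1 returns `to` exactly. Columns stay unit-norm.
slerp_columns <- function(from, to, t) {
  out <- from
  for (j in seq_len(ncol(from))) {
    u <- from[, j]; v <- to[, j]
    d <- max(-1, min(1, sum(u * v)))
    omega <- acos(d)
    if (omega < 1e-12) { out[, j] <- v; next }
    out[, j] <- (sin((1 - t) * omega) * u + sin(t * omega) * v) / sin(omega)
  }
  out
}

# Source waveforms: n_sources x Nt. Source k replays the harmonic series with
# a (k-1)*pi/2 phase offset so multiple sources are linearly independent.
source_waveforms <- function(subject, f_stim_hz, fs_hz, n_samples) {
  tt <- (seq_len(n_samples) - 1) / fs_hz
  a <- subject$harmonic_amplitudes
  ph <- subject$harmonic_phases
  n_src <- ncol(subject$mixing_matrix)
  S <- matrix(0, n_src, n_samples)
  for (k in seq_len(n_src)) {
    off <- (k - 1) * pi / 2
    for (h in seq_along(a)) {
      if (a[h] == 0) next
      S[k, ] <- S[k, ] + a[h] * sin(2 * pi * h * f_stim_hz * tt + ph[h] + off)
    }
  }
  S
}

# 1/f-amplitude-shaped noise via FFT filtering of white noise (one row).
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))          # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)            # mirror for the negative frequencies
  shaped <- W / sqrt(f)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x - mean(x)
}

#' Simulate one SSVEP trial
#'
#' Generates `X = A %*% S + noise`: the subject's sources (sinusoids at the
#' stimulation frequency and its harmonics) mixed onto the channels through
#' the subject's mixing matrix, plus broadband noise scaled so the realized
#' aggregate channel signal-to-noise power ratio equals `subject$snr_db`
#' (noise omitted entirely when `snr_db` is infinite).
#'
#' @param subject A `subject_model`.
#' @param f_stim_hz Stimulation frequency; must be one of
#'   `config$stim_frequencies_hz`.
#' @param config A `sim_config`.
#' @param seed Integer seed for the noise stream of this trial.
#' @param block_index Block label carried into the trial metadata.
#'
#' @return An `ssvep_trial`.
#' @export
simulate_trial <- function(subject, f_stim_hz, config, seed,
                           block_index = 1L) {
  if (!any(abs(f_stim_hz - config$stim_frequencies_hz) < 1e-9))
    stop("f_stim_hz is not one of config$stim_frequencies_hz", call. = FALSE)
  if (!all(is.finite(subject$mixing_matrix)) ||
      !all(is.finite(subject$harmonic_amplitudes)))
    stop("non-finite subject parameters", call. = FALSE)
  nt <- round(config$fs_hz * config$trial_duration_s)
  S <- source_waveforms(subject, f_stim_hz, config$fs_hz, nt)
  X <- subject$mixing_matrix %*% S
  if (is.finite(subject$snr_db)) {
    p_sig <- mean(X^2)
    # a silent source model (all-zero amplitudes) degenerates to pure noise
    sigma2 <- if (p_sig > 0) p_sig / 10^(subject$snr_db / 10) else 1
    noise <- with_seed(seed, {
      N <- matrix(stats::rnorm(nrow(X) * nt), nrow(X), nt)
      if (config$noise_model == "white_plus_pink") {
        P <- t(vapply(seq_len(nrow(X)), function(i) pink_noise(nt), numeric(nt)))
        N <- N / sqrt(mean(N^2)) + P / sqrt(mean(P^2))   # equal power split
      }
      N
    })
    noise <- noise * sqrt(sigma2 / mean(noise^2))
    X <- X + noise
  }
  ssvep_trial(X, config$fs_hz, subject$subject_id, block_index, f_stim_hz)
}

# The subject models a configuration implies: per-subject random mixing
# matrices spherically pulled toward a shared base matrix by
# subject_separation (1 = everyone identical).
build_subject_models <- function(config) {
  base <- make_subject(stream_seed(config$seed, 0L), config$n_channels,
                       config$n_sources, config$snr_db,
                       config$harmonic_amplitudes)
  lapply(seq_len(config$n_subjects), function(s) {
    subj <- make_subject(stream_seed(config$seed, s), config$n_channels,
                         config$n_sources, config$snr_db,
                         config$harmonic_amplitudes, subject_id = s)
    subj$mixing_matrix <- slerp_columns(subj$mixing_matrix,
                                        base$mixing_matrix,
                                        config$subject_separation)
    subj
  })
}

#' Simulate a complete multi-subject SSVEP data set
#'
#' Produces one trial per (subject, block, frequency) cell. Mixing matrices
#' are spherically interpolated between per-subject random matrices and a
#' shared base matrix according to `subject_separation`, and noise streams
#' are split per cell so enlarging the design never changes existing trials.
#' The result is a pure function of the configuration (including its seed).
#'
#' @param config A `sim_config`.
#' @return An `ssvep_trialset` with
#'   `n_subjects * n_blocks * length(stim_frequencies_hz)` trials.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- build_subject_models(config)
  trials <- list()
  i <- 0L
  for (s in seq_len(config$n_subjects))
    for (b in seq_len(config$n_blocks))
      for (fi in seq_along(config$stim_frequencies_hz)) {
        i <- i + 1L
        trials[[i]] <- simulate_trial(
          subjects[[s]], config$stim_frequencies_hz[fi], config,
          seed = stream_seed(config$seed, s, b, fi), block_index = b)
      }
  ssvep_trialset(trials, config$n_subjects, config$n_blocks,
                 config$stim_frequencies_hz)
}
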