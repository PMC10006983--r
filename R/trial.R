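#' SSVEP trial container
#'
#' A single stimulus-locked multichannel EEG epoch together with the metadata
#' every downstream stage needs: sampling rate, subject identity, block index
#' and the flicker frequency of the stimulus the subject attended.
#'
#' @param data Numeric matrix, channels x samples (microvolt scale).
#' @param fs_hz Sampling rate in Hz.
#' @param subject_id Integer subject index (1..Ns).
#' @param block_index Integer block (repetition sweep) index.
#' @param stim_freq_hz Stimulation (flicker) frequency in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#'   Defaults to `"ch1".."chN"`.
#'
#' @return An object of class `ssvep_trial`.
#' @export
ssvep_trial <- function(data, fs_hz, subject_id, block_index, stim_freq_hz,
                        channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  if (any(!is.finite(data)))
    stop("trial data contain non-finite values", call. = FALSE)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("`fs_hz` must be a positive scalar", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("`channel_names` length must equal the number of rows", call. = FALSE)
  rownames(data) <- channel_names
  structure(
    list(data = data, fs_hz = as.numeric(fs_hz),
         subject_id = as.integer(subject_id),
         block_index = as.integer(block_index),
         stim_freq_hz = as.numeric(stim_freq_hz),
         channel_names = as.character(channel_names)),
    class = "ssvep_trial")
}

#' @export
print.ssvep_trial <- function(x, ...) {
  cat(sprintf(
    "<ssvep_trial> subject %d, block %d, %.4g Hz stimulus\n  %d channels x %d samples @ %g Hz (%.3g s)\n",
    x$subject_id, x$block_index, x$stim_freq_hz,
    nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz))
  invisible(x)
}

#' @export
dim.ssvep_trial <- function(x) dim(x$data)

#' Number of samples / channels of a trial
#' @param trial An `ssvep_trial`.
#' @return Integer count.
#' @export
n_samples <- function(trial) ncol(trial$data)

#' @rdname n_samples
#' @export
n_channels <- function(trial) nrow(trial$data)

#' Collection of SSVEP trials
#'
#' Groups trials from a complete design: `n_subjects` subjects x `n_blocks`
#' blocks x `length(frequencies)` stimulation frequencies. The container does
#' not enforce completeness on construction (loaders may produce partial sets);
#' the leave-one-block-out fold builder does, because the protocol requires one
#' trial per (subject, block) cell at the analysed frequency.
#'
#' @param trials List of `ssvep_trial` objects.
#' @param n_subjects,n_blocks Integers describing the design.
#' @param frequencies Numeric vector of stimulation frequencies present.
#' @return An object of class `ssvep_trialset`.
#' @export
ssvep_trialset <- function(trials, n_subjects, n_blocks, frequencies) {
  if (!length(trials)) stop("empty trial list", call. = FALSE)
  ok <- vapply(trials, inherits, logical(1), "ssvep_trial")
  if (!all(ok)) stop("all elements must be ssvep_trial objects", call. = FALSE)
  sid <- vapply(trials, `[[`, integer(1), "subject_id")
  if (any(sid < 1L | sid > n_subjects))
    stop("subject_id outside 1..n_subjects", call. = FALSE)
  structure(
    list(trials = trials, n_subjects = as.integer(n_subjects),
         n_blocks = as.integer(n_blocks),
         frequencies = as.numeric(frequencies)),
    class = "ssvep_trialset")
}

#' @export
print.ssvep_trialset <- function(x, ...) {
  cat(sprintf(
    "<ssvep_trialset> %d trials: %d subjects, %d blocks, %d frequency(ies)\n",
    length(x$trials), x$n_subjects, x$n_blocks, length(x$frequencies)))
  invisible(x)
}

#' @export
length.ssvep_trialset <- function(x) length(x$trials)

#' Subset a trial set by a predicate on trial metadata
#'
#' @param ts An `ssvep_trialset`.
#' @param subject,block,stim_freq Optional filters; `NULL` keeps all.
#' @return A new `ssvep_trialset` (design metadata preserved).
#' @export
subset_trials <- function(ts, subject = NULL, block = NULL, stim_freq = NULL) {
  keep <- rep(TRUE, length(ts$trials))
  if (!is.null(subject))
    keep <- keep & vapply(ts$trials, `[[`, integer(1), "subject_id") %in% subject
  if (!is.null(block))
    keep <- keep & vapply(ts$trials, `[[`, integer(1), "block_index") %in% block
  if (!is.null(stim_freq)) {
    f <- vapply(ts$trials, `[[`, numeric(1), "stim_freq_hz")
    keep <- keep & vapply(f, function(fi) any(abs(fi - stim_freq) < 1e-9), logical(1))
  }
  if (!any(keep)) stop("subset is empty", call. = FALSE)
  ssvep_trialset(ts$trials[keep], ts$n_subjects, ts$n_blocks, ts$frequencies)
}

trial_field <- function(ts, field, mode = numeric(1)) {
  vapply(ts$trials, `[[`, mode, field)
}
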