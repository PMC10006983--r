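#' Band and filterbank specifications
#'
#' `band_spec()` describes one pass band; `filter_bank()` a set of bands
#' sharing a Butterworth design applied forward-backward (zero net phase).
#' `default_filterbank()` partitions an analysis range into `n_bands`
#' contiguous equal-width bands — the default 8-30 Hz range split into four
#' bands (8-13.5, 13.5-19, 19-24.5, 24.5-30 Hz) suits occipital SSVEP work.
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high`.
#' @return `band_spec()`: a `band_spec`; `filter_bank()` /
#'   `default_filterbank()`: a `filter_bank`.
#' @export
band_spec <- function(low_hz, high_hz) {
  if (!(low_hz > 0 && high_hz > low_hz))
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  structure(list(low_hz = as.numeric(low_hz), high_hz = as.numeric(high_hz)),
            class = "band_spec")
}

#' @rdname band_spec
#' @param bands List of `band_spec` objects.
#' @param order Butterworth order of the one-way design (the forward-backward
#'   application doubles the effective order).
#' @export
filter_bank <- function(bands, order = 4L) {
  if (!length(bands)) stop("need at least one band", call. = FALSE)
  if (inherits(bands, "band_spec")) bands <- list(bands)
  ok <- vapply(bands, inherits, logical(1), "band_spec")
  if (!all(ok)) stop("`bands` must be band_spec objects", call. = FALSE)
  structure(list(bands = bands, filter_family = "butterworth",
                 order = as.integer(order), zero_phase = TRUE),
            class = "filter_bank")
}

#' @rdname band_spec
#' @param n_bands Number of contiguous equal-width bands.
#' @export
default_filterbank <- function(low_hz = 8, high_hz = 30, n_bands = 4L,
                               order = 4L) {
  edges <- seq(low_hz, high_hz, length.out = n_bands + 1L)
  filter_bank(lapply(seq_len(n_bands),
                     function(b) band_spec(edges[b], edges[b + 1L])),
              order = order)
}

#' @export
print.filter_bank <- function(x, ...) {
  e <- vapply(x$bands, function(b) sprintf("%.4g-%.4g", b$low_hz, b$high_hz),
              character(1))
  cat(sprintf("<filter_bank> %d band(s) [%s] Hz, Butterworth order %d, zero-phase\n",
              length(x$bands), paste(e, collapse = ", "), x$order))
  invisible(x)
}

# IIR difference-equation filtering (direct form) of a numeric vector.
iir_pass <- function(b, a, x) {
  as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
}

# Forward-backward IIR filtering with odd-reflection padding of length
# 3*(order+1) at each end; the padding suppresses the start-up transient a
# plain two-pass filter would leave on short epochs.
iir_filtfilt <- function(b, a, x, order) {
  pad <- 3L * (order + 1L)
  n <- length(x)
  if (n <= pad)
    stop(sprintf("trial too short for zero-phase filtering (need > %d samples)", pad),
         call. = FALSE)
  head_pad <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- c(head_pad, x, tail_pad)
  y <- iir_pass(b, a, y)
  y <- rev(iir_pass(b, a, rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Zero-phase band-pass filter a trial
#'
#' Applies a Butterworth band-pass forward and backward (zero net phase;
#' effective order twice `order`) to every channel, with odd-reflection
#' padding of `3 * (order + 1)` samples at each end to tame edge
#' transients. Rows are re-centred afterwards, preserving the convention
#' that trials are zero-mean per channel.
#'
#' @param trial An `ssvep_trial`.
#' @param band A `band_spec`; `high_hz` must stay below Nyquist.
#' @param order One-way Butterworth order (default 4).
#' @return A filtered `ssvep_trial` of identical shape and metadata.
#' @export
bandpass_zero_phase <- function(trial, band, order = 4L) {
  nyq <- trial$fs_hz / 2
  if (band$high_hz >= nyq)
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 band$high_hz, nyq), call. = FALSE)
  bf <- signal::butter(order, c(band$low_hz, band$high_hz) / nyq, type = "pass")
  X <- trial$data
  for (i in seq_len(nrow(X)))
    X[i, ] <- iir_filtfilt(bf$b, bf$a, X[i, ], order)
  X <- X - rowMeans(X)
  out <- trial
  out$data <- X
  rownames(out$data) <- trial$channel_names
  out
}

#' Expand a trial through a filterbank
#'
#' @param trial An `ssvep_trial`.
#' @param bank A `filter_bank`.
#' @return A list of filtered trials, one per band, in band order.
#' @export
apply_filterbank <- function(trial, bank) {
  lapply(bank$bands, function(b) bandpass_zero_phase(trial, b, bank$order))
}

#' Window specification
#'
#' @param tw_s Analysis window length TW in seconds.
#' @param onset_offset_s Offset of the window start from trial onset
#'   (seconds); public SSVEP benchmarks often include a visual-latency
#'   offset, synthetic trials do not.
#' @return A `window_spec`.
#' @export
window_spec <- function(tw_s, onset_offset_s = 0) {
  if (tw_s <= 0) stop("tw_s must be positive", call. = FALSE)
  if (onset_offset_s < 0) stop("onset offset must be non-negative", call. = FALSE)
  structure(list(tw_s = as.numeric(tw_s),
                 onset_offset_s = as.numeric(onset_offset_s)),
            class = "window_spec")
}

#' Cut a trial down to an analysis window
#'
#' Keeps samples `[round(onset * fs), round(onset * fs) + round(tw * fs))`;
#' metadata is preserved. Filtering should precede windowing so short
#' windows are not contaminated by filter edge effects.
#'
#' @param trial An `ssvep_trial`.
#' @param window A `window_spec` that fits inside the trial.
#' @return A shorter `ssvep_trial`.
#' @export
window_trial <- function(trial, window) {
  start <- round(window$onset_offset_s * trial$fs_hz)
  len <- round(window$tw_s * trial$fs_hz)
  if (start + len > ncol(trial$data))
    stop("window extends beyond the trial", call. = FALSE)
  out <- trial
  out$data <- trial$data[, seq(start + 1L, start + len), drop = FALSE]
  out
}

#' Select (and reorder) channels of a trial
#'
#' @param trial An `ssvep_trial`.
#' @param names Channel names to keep, in the desired output order.
#' @return An `ssvep_trial` with the requested rows.
#' @export
select_channels <- function(trial, names) {
  idx <- match(names, trial$channel_names)
  if (anyNA(idx))
    stop(sprintf("unknown channel(s): %s",
                 paste(names[is.na(idx)], collapse = ", ")), call. = FALSE)
  out <- trial
  out$data <- trial$data[idx, , drop = FALSE]
  out$channel_names <- trial$channel_names[idx]
  rownames(out$data) <- out$channel_names
  out
}
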