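#' Trace-normalized spatial covariance of a trial
#'
#' Returns `X %*% t(X) / trace(X %*% t(X))`. Trace normalization removes
#' per-trial amplitude differences so trials contribute equally to the class
#' covariance regardless of their overall power.
#'
#' @param trial An `ssvep_trial` or a channels x samples numeric matrix
#'   (rows assumed centred).
#' @return A symmetric positive semidefinite matrix with unit trace.
#' @export
spatial_covariance <- function(trial) {
  X <- if (inherits(trial, "ssvep_trial")) trial$data else trial
  C <- tcrossprod(X)
  tr <- sum(diag(C))
  if (tr <= 0) stop("degenerate trial: zero total power", call. = FALSE)
  C / tr
}

#' Class covariance with diagonal loading
#'
#' Arithmetic mean of per-trial trace-normalized covariances, shrunk toward
#' the scaled identity: `(1 - gamma) * C + gamma * (tr(C)/Nch) * I`. The
#' tiny default loading guards invertibility of the "rest" covariance in
#' the generalized eigenproblem; `gamma = 1` collapses to `I/Nch`.
#'
#' @param trials List of `ssvep_trial` (or matrices) with equal channel count.
#' @param gamma Shrinkage weight in `[0, 1]`.
#' @return A symmetric positive definite matrix.
#' @export
class_covariance <- function(trials, gamma = 1e-6) {
  if (!length(trials)) stop("empty trial list", call. = FALSE)
  covs <- lapply(trials, spatial_covariance)
  average_covariances(covs, gamma)
}

average_covariances <- function(covs, gamma = 1e-6) {
  C <- Reduce(`+`, covs) / length(covs)
  n <- nrow(C)
  (1 - gamma) * C + gamma * (sum(diag(C)) / n) * diag(n)
}

# Deterministic sign: make each column's largest-magnitude entry positive.
fix_signs <- function(W) {
  for (j in seq_len(ncol(W))) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  W
}

#' Common-spatial-pattern filter pair from two class covariances
#'
#' Solves the generalized eigenvalue problem `C1 w = lambda C2 w` — the
#' stationarity condition of the variance-ratio objective
#' `J(w) = (w' C1 w) / (w' C2 w)` — by whitening `C2` and
#' eigendecomposing the whitened `C1`. Filters are normalized so
#' `w' C2 w = 1`, and the `p` eigenvectors from each end of the spectrum
#' are kept: large eigenvalues maximize target-class variance, small ones
#' minimize it, and both ends discriminate.
#'
#' @param c1,c2 Symmetric PSD covariance matrices (target class / rest);
#'   `c2` must be invertible (apply diagonal loading upstream).
#' @param p Filters kept per spectrum end; `2 * p <= Nch`.
#' @return List with `W` (`Nch x 2p`; first `p` columns for the largest
#'   eigenvalues, last `p` for the smallest), `eigenvalues` (all `Nch`,
#'   descending), and `W_full` (all generalized eigenvectors).
#' @export
csp_pair <- function(c1, c2, p) {
  n <- nrow(c1)
  if (2L * p > n) stop("2*p exceeds the number of channels", call. = FALSE)
  if (max(abs(c1 - t(c1))) > 1e-10 || max(abs(c2 - t(c2))) > 1e-10)
    stop("covariances must be symmetric", call. = FALSE)
  e2 <- eigen((c2 + t(c2)) / 2, symmetric = TRUE)
  if (min(e2$values) <= 0)
    stop("c2 is singular; increase diagonal loading", call. = FALSE)
  P <- diag(1 / sqrt(e2$values), n) %*% t(e2$vectors)     # P c2 P' = I
  Sw <- P %*% c1 %*% t(P)
  es <- eigen((Sw + t(Sw)) / 2, symmetric = TRUE)         # descending
  W_full <- fix_signs(t(P) %*% es$vectors)
  lambda <- es$values
  # stable tie handling: among (numerically) equal eigenvalues order by the
  # row index of each column's largest-magnitude component
  ord <- order(-lambda, vapply(seq_len(n), function(j) which.max(abs(W_full[, j])),
                               integer(1)))
  lambda <- lambda[ord]
  W_full <- W_full[, ord, drop = FALSE]
  keep <- c(seq_len(p), seq(n - p + 1L, n))
  list(W = W_full[, keep, drop = FALSE], eigenvalues = lambda, W_full = W_full)
}

# Internal band expansion of a trial set: filters every trial through every
# band once (then windows), so leave-one-block-out folds never refilter.
# Returns list(bank, window, meta, data[[b]][[i]] = channels x samples matrix,
# cov[[b]][[i]] = trace-normalized covariance).
band_expand_set <- function(ts, bank, window = NULL) {
  B <- length(bank$bands)
  data <- vector("list", B)
  covs <- vector("list", B)
  for (b in seq_len(B)) {
    data[[b]] <- lapply(ts$trials, function(tr) {
      f <- bandpass_zero_phase(tr, bank$bands[[b]], bank$order)
      if (!is.null(window)) f <- window_trial(f, window)
      f$data
    })
    covs[[b]] <- lapply(data[[b]], spatial_covariance)
  }
  list(bank = bank, window = window,
       subject = trial_field(ts, "subject_id", integer(1)),
       block = trial_field(ts, "block_index", integer(1)),
       stim_freq = trial_field(ts, "stim_freq_hz"),
       n_subjects = ts$n_subjects,
       channel_names = ts$trials[[1]]$channel_names,
       data = data, cov = covs)
}

# Fit the one-vs-rest filters from precomputed per-trial covariances.
fit_ovr_from_covs <- function(covs, subject, n_subjects, bank, p,
                              gamma = 1e-6, channel_names = NULL) {
  B <- length(bank$bands)
  filters <- vector("list", n_subjects)
  eigenvalues <- vector("list", n_subjects)
  for (cls in seq_len(n_subjects)) {
    filters[[cls]] <- vector("list", B)
    eigenvalues[[cls]] <- vector("list", B)
    own <- which(subject == cls)
    rest <- which(subject != cls)
    if (!length(own))
      stop(sprintf("subject %d has no training trials", cls), call. = FALSE)
    for (b in seq_len(B)) {
      c1 <- average_covariances(covs[[b]][own], gamma)
      c2 <- average_covariances(covs[[b]][rest], gamma)
      if (kappa(c2, exact = FALSE) > 1e10) {
        warning("ill-conditioned rest covariance; raising diagonal loading")
        c2 <- average_covariances(covs[[b]][rest], gamma = 1e-3)
      }
      sol <- csp_pair(c1, c2, p)
      filters[[cls]][[b]] <- sol$W
      eigenvalues[[cls]][[b]] <- sol$eigenvalues
    }
  }
  structure(
    list(bands = bank, p = as.integer(p), filters = filters,
         eigenvalues = eigenvalues, n_classes = as.integer(n_subjects),
         n_channels = nrow(filters[[1]][[1]]),
         channel_names = channel_names,
         feature_dim = as.integer(n_subjects * B * 2L * p),
         gamma = gamma, format_version = "csp-1"),
    class = "csp_model")
}

#' Fit one-vs-rest filterbank CSP filters
#'
#' For every subject (class) and every filterbank band, estimates the
#' target covariance from that subject's band-filtered trials and the rest
#' covariance from everyone else's, and solves the CSP generalized
#' eigenproblem. With `Np` subjects, `B` bands and `2p` filters per
#' problem the resulting feature dimension is `Np * B * 2 * p`.
#'
#' @param trainset An `ssvep_trialset`; all trials at one stimulation
#'   frequency (identification is per-frequency), at least two subjects,
#'   at least one trial each.
#' @param bank A `filter_bank`.
#' @param p Filters kept per spectrum end (default 2).
#' @param window Optional `window_spec` applied after filtering.
#' @param gamma Diagonal loading weight (default 1e-6).
#' @return A `csp_model`.
#' @export
fit_fbcsp_ovr <- function(trainset, bank, p = 2L, window = NULL,
                          gamma = 1e-6) {
  freqs <- unique(trial_field(trainset, "stim_freq_hz"))
  if (length(freqs) > 1L)
    stop("all training trials must share one stimulation frequency",
         call. = FALSE)
  subj <- trial_field(trainset, "subject_id", integer(1))
  if (length(unique(subj)) < 2L)
    stop("need at least two subjects", call. = FALSE)
  be <- band_expand_set(trainset, bank, window)
  fit_ovr_from_covs(be$cov, be$subject, trainset$n_subjects, bank, p,
                    gamma, be$channel_names)
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf(
    "<csp_model> %d classes x %d bands x %d filters -> %d features (p = %d)\n",
    x$n_classes, length(x$bands$bands), 2L * x$p, x$feature_dim, x$p))
  invisible(x)
}

# Population (1/Nt) variance of each column.
col_pop_var <- function(Z) colMeans(Z^2) - colMeans(Z)^2

# Log-variance features from one trial's precomputed band matrices.
features_from_banded <- function(band_mats, model, eps = 1e-12) {
  B <- length(model$bands$bands)
  out <- numeric(model$feature_dim)
  clamped <- FALSE
  k <- 0L
  for (cls in seq_len(model$n_classes)) {
    for (b in seq_len(B)) {
      Z <- crossprod(band_mats[[b]], model$filters[[cls]][[b]])  # Nt x 2p
      v <- col_pop_var(Z)
      if (any(v < eps)) { clamped <- TRUE; v <- pmax(v, eps) }
      out[k + seq_along(v)] <- log(v)
      k <- k + length(v)
    }
  }
  attr(out, "clamped") <- clamped
  out
}

#' Extract an FBCSP log-variance feature vector
#'
#' Band-filters the trial through the model's filterbank, projects each band
#' through every class's spatial filters (`Z = t(X_b) %*% W`), and takes the
#' natural log of the population (1/Nt) variance of each projected column.
#' Features are concatenated class-major, then band, then filter column.
#' Variances below `1e-12` are clamped there (flagged via the `clamped`
#' field) before the log.
#'
#' @param trial An `ssvep_trial` with the model's channel count.
#' @param model A `csp_model`.
#' @param window Optional `window_spec` applied after filtering (use the
#'   same window the model was fitted with).
#' @return A `feature_vector`: `values` (length `feature_dim`),
#'   `subject_label`, `block_index`, `stim_freq_hz`, `clamped`.
#' @export
extract_features <- function(trial, model, window = NULL) {
  if (nrow(trial$data) != model$n_channels)
    stop(sprintf("extract_features: trial has %d channels, model expects %d",
                 nrow(trial$data), model$n_channels), call. = FALSE)
  mats <- lapply(model$bands$bands, function(bd) {
    f <- bandpass_zero_phase(trial, bd, model$bands$order)
    if (!is.null(window)) f <- window_trial(f, window)
    f$data
  })
  vals <- features_from_banded(mats, model)
  structure(
    list(values = as.numeric(vals), subject_label = trial$subject_id,
         block_index = trial$block_index, stim_freq_hz = trial$stim_freq_hz,
         clamped = attr(vals, "clamped")),
    class = "feature_vector")
}

# Feature matrix (n_trials x feature_dim) for chosen indices of a
# band-expanded set under a fitted model.
feature_matrix_from_banded <- function(be, model, idx = seq_along(be$subject)) {
  X <- matrix(0, length(idx), model$feature_dim)
  for (i in seq_along(idx)) {
    mats <- lapply(be$data, `[[`, idx[i])
    X[i, ] <- features_from_banded(mats, model)
  }
  list(x = X, y = be$subject[idx], block = be$block[idx])
}
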