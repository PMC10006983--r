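#' Leave-one-block-out folds
#'
#' The identification protocol: at one stimulation frequency, every fold
#' holds out one complete block (one trial per subject) for testing and
#' trains on all remaining blocks. Requires the design to be complete —
#' exactly one trial per (subject, block) cell at that frequency.
#'
#' @param trialset An `ssvep_trialset`.
#' @param stim_freq The stimulation frequency to analyse.
#' @return List of `n_blocks` folds, each `list(train =, test =)` of
#'   `ssvep_trialset`s; test sets are disjoint and jointly exhaust the set.
#' @export
lobo_folds <- function(trialset, stim_freq) {
  sub <- subset_trials(trialset, stim_freq = stim_freq)
  check_complete_design(sub)
  blocks <- sort(unique(trial_field(sub, "block_index", integer(1))))
  lapply(blocks, function(bk) {
    list(train = subset_trials(sub, block = setdiff(blocks, bk)),
         test = subset_trials(sub, block = bk),
         fold_index = bk)
  })
}

check_complete_design <- function(ts) {
  sid <- trial_field(ts, "subject_id", integer(1))
  blk <- trial_field(ts, "block_index", integer(1))
  tab <- table(factor(sid, levels = seq_len(ts$n_subjects)),
               factor(blk, levels = sort(unique(blk))))
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "incomplete design: subject %s has %d trial(s) in block %s (need exactly 1)",
      rownames(tab)[bad[1]], tab[bad[1], bad[2]], colnames(tab)[bad[2]]),
      call. = FALSE)
  }
  invisible(ts)
}

#' Confusion matrix and correct recognition rate
#'
#' `crr()` is the average of the diagonal of the row-normalized confusion
#' matrix, in percent — the balanced per-class recall, which coincides
#' with plain accuracy in the balanced leave-one-block-out design.
#'
#' @param true,predicted Integer label vectors of equal length.
#' @param n_classes Number of classes (labels in `1..n_classes`).
#' @return `confusion_matrix()`: integer matrix (rows = true class);
#'   `crr()`: a percentage in `[0, 100]`.
#' @export
confusion_matrix <- function(true, predicted, n_classes) {
  if (length(true) != length(predicted))
    stop("label vectors differ in length", call. = FALSE)
  as.matrix(table(factor(true, levels = seq_len(n_classes)),
                  factor(predicted, levels = seq_len(n_classes))))
}

#' @rdname confusion_matrix
#' @export
crr <- function(true, predicted, n_classes) {
  if (!length(true)) stop("empty prediction set", call. = FALSE)
  cm <- confusion_matrix(true, predicted, n_classes)
  rs <- rowSums(cm)
  if (any(rs == 0))
    stop("a class has no true instances; its recall is undefined", call. = FALSE)
  100 * mean(diag(cm) / rs)
}

#' Usability measure U
#'
#' `U = N * CRR / (Tr + K * Te)`: identification performance discounted by
#' acquisition burden — training duration `Tr` (seconds), electrode count
#' `K`, and test duration `Te` (seconds) — and scaled by the population
#' size `N` it supports. CRR enters on the percent scale. `Tr` defaults to
#' 25 s (five training blocks of 5 s trials in the six-block design).
#'
#' @param n_subjects N, number of enrolled subjects.
#' @param n_electrodes K, number of electrodes.
#' @param crr_percent CRR in percent (0-100).
#' @param train_duration_s Tr in seconds (default 25).
#' @param test_duration_s Te in seconds.
#' @return The usability value (dimensionless).
#' @export
usability <- function(n_subjects, n_electrodes, crr_percent,
                      train_duration_s = 25, test_duration_s) {
  den <- train_duration_s + n_electrodes * test_duration_s
  if (any(den <= 0)) stop("non-positive denominator", call. = FALSE)
  if (any(n_subjects <= 0) || any(n_electrodes <= 0))
    stop("N and K must be positive", call. = FALSE)
  n_subjects * crr_percent / den
}

#' One-way analysis of variance
#'
#' Classical fixed-effects between/within decomposition with
#' `df = (g - 1, n - g)`, as used to compare classifiers' CRR values
#' across stimulation frequencies. Degenerate case: zero within-group
#' variance with unequal means reports `F = Inf`.
#'
#' @param groups List of numeric vectors (>= 2 groups of >= 2 values).
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  dfb <- length(groups) - 1L
  dfw <- length(values) - length(groups)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  means <- vapply(groups, mean, numeric(1))
  if (ssw == 0) {
    if (max(means) - min(means) > 0)
      return(list(F = Inf, df_between = dfb, df_within = dfw, p = 0))
    return(list(F = 0, df_between = dfb, df_within = dfw, p = 1))
  }
  ot <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ot$statistic),
       df_between = as.integer(ot$parameter[1]),
       df_within = as.integer(ot$parameter[2]),
       p = unname(ot$p.value))
}

#' Pairwise post hoc comparisons
#'
#' Welch two-sample t-tests for every pair of groups with Bonferroni
#' correction — one reasonable reading of an unspecified "post hoc
#' analysis" following a one-way ANOVA.
#'
#' @param groups Named list of numeric vectors.
#' @return Data frame of pairs with raw and Bonferroni-adjusted p-values.
#' @export
posthoc_pairwise <- function(groups) {
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- apply(pairs, 2, function(ij) {
    tt <- stats::t.test(groups[[ij[1]]], groups[[ij[2]]])
    c(p = tt$p.value)
  })
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             p_raw = as.numeric(res),
             p_bonferroni = pmin(1, as.numeric(res) * ncol(pairs)))
}

#' Run leave-one-block-out identification at one frequency
#'
#' The full pipeline per fold: fit one-vs-rest filterbank CSP filters on
#' the training blocks, extract log-variance features for train and test,
#' z-score with training statistics, train the requested classifier, and
#' predict the held-out block. Per-frequency CRR is computed on the
#' confusion matrix pooled over folds (identical to the mean of per-fold
#' CRRs in this balanced design).
#'
#' @param trialset An `ssvep_trialset`.
#' @param stim_freq Stimulation frequency to analyse.
#' @param bank A `filter_bank` (default [default_filterbank()]).
#' @param p CSP filters kept per spectrum end (default 2).
#' @param window Optional `window_spec` (applied after filtering).
#' @param classifier `"dfn"`, `"svm"` or `"knn"`.
#' @param dfn DFN configuration (a `dfn_config`); its seed is offset by
#'   the fold index so folds are independent but reproducible.
#' @param baseline A `baseline_config` for the comparators.
#' @param gamma Covariance diagonal loading.
#' @return An `eval_result`: pooled `confusion`, `crr_percent`, per-fold
#'   results, and the run description.
#' @export
run_lobo <- function(trialset, stim_freq, bank = default_filterbank(),
                     p = 2L, window = NULL,
                     classifier = c("dfn", "svm", "knn"),
                     dfn = dfn_config(), baseline = baseline_config(),
                     gamma = 1e-6) {
  classifier <- match.arg(classifier)
  sub <- subset_trials(trialset, stim_freq = stim_freq)
  check_complete_design(sub)
  be <- band_expand_set(sub, bank, window)
  blocks <- sort(unique(be$block))
  ns <- sub$n_subjects
  pooled_true <- integer(0); pooled_pred <- integer(0)
  fold_results <- list()
  for (k in seq_along(blocks)) {
    te_idx <- which(be$block == blocks[k])
    tr_idx <- which(be$block != blocks[k])
    covs_tr <- lapply(be$cov, function(l) l[tr_idx])
    model <- fit_ovr_from_covs(covs_tr, be$subject[tr_idx], ns, bank, p,
                               gamma, be$channel_names)
    tr <- feature_matrix_from_banded(be, model, tr_idx)
    te <- feature_matrix_from_banded(be, model, te_idx)
    st <- fit_standardizer(tr$x)
    x_tr <- apply_standardizer(st, tr$x)
    x_te <- apply_standardizer(st, te$x)
    pred <- switch(classifier,
      dfn = {
        cfg <- dfn; cfg$seed <- dfn$seed + k
        net <- build_dfn(model$feature_dim, ns, cfg)
        fit <- train_dfn(net, x_tr, tr$y, blocks = tr$block)
        predict(fit$model, x_te)$labels
      },
      svm = predict(fit_linear_svm(x_tr, tr$y, baseline), x_te)$labels,
      knn = predict(fit_knn(x_tr, tr$y, baseline), x_te)$labels)
    cm <- confusion_matrix(te$y, pred, ns)
    fold_results[[k]] <- list(fold_index = blocks[k], confusion = cm,
                              crr_percent = 100 * mean(diag(cm) / rowSums(cm)))
    pooled_true <- c(pooled_true, te$y)
    pooled_pred <- c(pooled_pred, pred)
  }
  pooled <- confusion_matrix(pooled_true, pooled_pred, ns)
  structure(
    list(confusion = pooled,
         crr_percent = crr(pooled_true, pooled_pred, ns),
         folds = fold_results, stim_freq_hz = stim_freq,
         tw_s = if (is.null(window)) NA_real_ else window$tw_s,
         classifier = classifier, n_test = length(pooled_true)),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s @ %.4g Hz%s: CRR %.4f%% over %d folds (%d trials)\n",
              x$classifier, x$stim_freq_hz,
              if (is.na(x$tw_s)) "" else sprintf(", TW %.2g s", x$tw_s),
              x$crr_percent, length(x$folds), x$n_test))
  invisible(x)
}

#' Sweep the analysis window length
#'
#' For each requested window length TW, runs the full leave-one-block-out
#' pipeline at every stimulation frequency in the set and averages the
#' per-frequency CRR. Shorter windows carry fewer SSVEP cycles, so CRR is
#' expected to grow with TW.
#'
#' @param trialset An `ssvep_trialset`.
#' @param tws Numeric vector of window lengths (seconds).
#' @param ... Passed to [run_lobo()] (`classifier`, `bank`, `p`, `dfn`, ...).
#' @param onset_offset_s Window onset offset (default 0).
#' @return Data frame with one row per TW: `tw_s`, `mean_crr`.
#' @export
sweep_tw <- function(trialset, tws, ..., onset_offset_s = 0) {
  rows <- lapply(tws, function(tw) {
    crrs <- vapply(trialset$frequencies, function(f) {
      run_lobo(trialset, f, window = window_spec(tw, onset_offset_s),
               ...)$crr_percent
    }, numeric(1))
    data.frame(tw_s = tw, mean_crr = mean(crrs))
  })
  do.call(rbind, rows)
}

#' Binomial chance band for CRR
#'
#' Central confidence band for the CRR of a uniform-random predictor over
#' `n_trials` pooled test trials with `n_classes` equiprobable classes.
#'
#' @param n_trials Pooled test-trial count.
#' @param n_classes Number of classes.
#' @param level Coverage (default 0.95).
#' @return `c(lower, upper)` in percent.
#' @export
crr_chance_band <- function(n_trials, n_classes, level = 0.95) {
  a <- (1 - level) / 2
  100 * c(stats::qbinom(a, n_trials, 1 / n_classes),
          stats::qbinom(1 - a, n_trials, 1 / n_classes)) / n_trials
}
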