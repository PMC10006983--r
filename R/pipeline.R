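#' End-to-end run configuration
#'
#' Bundles every knob of the identification pipeline — data source,
#' preprocessing, CSP, classifier and evaluation — under a single seed, so
#' a whole run is a pure function of its configuration.
#'
#' @param sim A `sim_config` describing the synthetic data source.
#' @param bank A `filter_bank`.
#' @param p CSP filters per spectrum end.
#' @param classifier `"dfn"`, `"svm"` or `"knn"` (enrollment always trains
#'   the network; benchmarks may sweep all three).
#' @param dfn A `dfn_config`.
#' @param baseline A `baseline_config`.
#' @param tws Window lengths (seconds) for duration sweeps; `NULL` uses the
#'   full trial.
#' @param train_duration_s Tr used in the usability measure (default 25 s:
#'   five training blocks of 5 s trials).
#' @param seed Master seed, propagated to the simulator and the network.
#' @return A `run_config`.
#' @export
run_config <- function(sim = sim_config(), bank = default_filterbank(),
                       p = 2L, classifier = c("dfn", "svm", "knn"),
                       dfn = dfn_config(), baseline = baseline_config(),
                       tws = NULL, train_duration_s = 25, seed = 1L) {
  classifier <- match.arg(classifier)
  sim$seed <- as.integer(seed)
  dfn$seed <- as.integer(seed)
  structure(
    list(sim = sim, bank = bank, p = as.integer(p), classifier = classifier,
         dfn = dfn, baseline = baseline, tws = tws,
         train_duration_s = train_duration_s, seed = as.integer(seed)),
    class = "run_config")
}

#' Enrollment: fit and persist the identification artifacts
#'
#' Simulates (or accepts) the enrollment recordings, fits the one-vs-rest
#' filterbank CSP filters on all trials at the first configured frequency,
#' extracts and standardizes the log-variance features, trains the
#' network, and stores the three artifacts the authentication phase
#' needs — the spatial filters, the feature store (with the standardizer),
#' and the network — plus a manifest recording the full configuration.
#'
#' @param config A `run_config`.
#' @param outdir Output directory (created if missing).
#' @param trialset Optional `ssvep_trialset`; by default simulated from
#'   `config$sim`.
#' @return Invisibly, the manifest list (artifact paths included).
#' @export
run_enrollment <- function(config, outdir, trialset = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory", call. = FALSE)
  if (is.null(trialset)) trialset <- simulate_dataset(config$sim)
  freq <- trialset$frequencies[1]
  sub <- subset_trials(trialset, stim_freq = freq)
  be <- band_expand_set(sub, config$bank, NULL)
  csp <- fit_ovr_from_covs(be$cov, be$subject, sub$n_subjects, config$bank,
                           config$p, channel_names = be$channel_names)
  fm <- feature_matrix_from_banded(be, csp)
  st <- fit_standardizer(fm$x)
  x <- apply_standardizer(st, fm$x)
  net <- build_dfn(csp$feature_dim, sub$n_subjects, config$dfn)
  fit <- train_dfn(net, x, fm$y, blocks = fm$block)
  paths <- file.path(outdir, c("csp_model.json", "features.json",
                               "dfn_model.json", "manifest.json"))
  save_csp_model(csp, paths[1])
  write_json_file(list(format_version = "features-1",
                       x = mat_to_list(fm$x), y = fm$y, block = fm$block,
                       standardizer = list(mean = unname(st$mean),
                                           sd = unname(st$sd)),
                       stim_freq_hz = freq),
                  paths[2])
  save_dfn_model(fit$model, paths[3])
  manifest <- list(format_version = "manifest-1",
                   created = format(Sys.time(), tz = "UTC"),
                   seed = config$seed, stim_freq_hz = freq,
                   selected_epoch = fit$history$selected_epoch,
                   artifacts = basename(paths[1:3]),
                   config = run_config_json(config))
  write_json_file(manifest, paths[4])
  invisible(manifest)
}

# Canonical (hash-free) JSON description of a run configuration.
run_config_json <- function(config) {
  list(sim = unclass(config$sim),
       bands = lapply(config$bank$bands, function(b) c(b$low_hz, b$high_hz)),
       filter_order = config$bank$order, p = config$p,
       classifier = config$classifier, dfn = unclass(config$dfn),
       baseline = unclass(config$baseline),
       tws = config$tws, train_duration_s = config$train_duration_s,
       seed = config$seed)
}

#' Authentication: identify trials against stored artifacts
#'
#' Loads the enrollment artifacts, applies the stored spatial filters and
#' standardizer to each incoming trial, and lets the stored network decide
#' the identity. Never retrains.
#'
#' @param artifact_dir Directory written by [run_enrollment()].
#' @param trials List of `ssvep_trial` objects (or an `ssvep_trialset`).
#' @return Data frame with one row per trial: `predicted`, `probability`
#'   (of the predicted identity), and `true` (NA when unknown).
#' @export
run_authentication <- function(artifact_dir, trials) {
  need <- file.path(artifact_dir, c("csp_model.json", "features.json",
                                    "dfn_model.json"))
  if (!all(file.exists(need)))
    stop("not enrolled: missing artifact(s) in ", artifact_dir, call. = FALSE)
  csp <- load_csp_model(need[1])
  feat <- jsonlite::read_json(need[2], simplifyVector = FALSE)
  st <- structure(list(mean = as.numeric(unlist(feat$standardizer$mean)),
                       sd = as.numeric(unlist(feat$standardizer$sd))),
                  class = "standardizer")
  net <- load_dfn_model(need[3])
  if (inherits(trials, "ssvep_trialset")) trials <- trials$trials
  rows <- lapply(trials, function(tr) {
    fv <- extract_features(tr, csp)
    pr <- predict(net, apply_standardizer(st, fv$values))
    data.frame(predicted = pr$labels,
               probability = max(pr$probabilities),
               true = if (is.null(tr$subject_id)) NA_integer_ else tr$subject_id)
  })
  do.call(rbind, rows)
}

#' Benchmark: CRR and usability tables over frequencies and durations
#'
#' Runs the leave-one-block-out pipeline for every classifier requested:
#' a per-frequency CRR table at full trial length, and — when `config$tws`
#' is set — per-TW tables of frequency-averaged CRR and of the usability
#' measure U (with `N = n_subjects`, `K = n_channels`,
#' `Tr = config$train_duration_s`, `Te = TW`).
#'
#' @param config A `run_config`.
#' @param trialset Optional pre-built `ssvep_trialset`.
#' @param classifiers Character vector of classifiers to compare.
#' @param outdir Optional directory; tables are written there as CSV.
#' @return List of data frames: `crr_by_frequency`, `crr_by_tw`, `u_by_tw`
#'   (the last two `NULL` without `tws`).
#' @export
run_benchmark <- function(config, trialset = NULL,
                          classifiers = config$classifier, outdir = NULL) {
  if (is.null(trialset)) trialset <- simulate_dataset(config$sim)
  freqs <- trialset$frequencies
  by_freq <- data.frame(stim_freq_hz = freqs)
  for (cl in classifiers) {
    by_freq[[cl]] <- vapply(freqs, function(f)
      run_lobo(trialset, f, bank = config$bank, p = config$p,
               classifier = cl, dfn = config$dfn,
               baseline = config$baseline)$crr_percent, numeric(1))
  }
  by_tw <- NULL; u_tw <- NULL
  if (!is.null(config$tws)) {
    by_tw <- data.frame(tw_s = config$tws)
    for (cl in classifiers) {
      sw <- sweep_tw(trialset, config$tws, bank = config$bank, p = config$p,
                     classifier = cl, dfn = config$dfn,
                     baseline = config$baseline)
      by_tw[[cl]] <- sw$mean_crr
    }
    u_tw <- data.frame(tw_s = config$tws)
    n_ch <- n_channels(trialset$trials[[1]])
    for (cl in classifiers)
      u_tw[[cl]] <- usability(trialset$n_subjects, n_ch, by_tw[[cl]],
                              config$train_duration_s, by_tw$tw_s)
  }
  out <- list(crr_by_frequency = by_freq, crr_by_tw = by_tw, u_by_tw = u_tw)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      if (!is.null(out[[nm]]))
        utils::write.csv(out[[nm]], file.path(outdir, paste0(nm, ".csv")),
                         row.names = FALSE)
  }
  out
}

#' Reference protocol settings of the two public SSVEP benchmarks
#'
#' The acquisition/design constants of the Tsinghua 40-target speller
#' benchmark and the PhysioNet Emotiv EPOC SSVEP collection, as used for
#' identification: subject count, block count, stimulus count, channel
#' subset, trial duration and analysis band. Exposed so benchmark scripts
#' and usability computations share one declaration; the data themselves
#' must be downloaded separately.
#'
#' @param dataset `"speller"` or `"epoc"`.
#' @return A list of protocol constants.
#' @export
dataset_settings <- function(dataset = c("speller", "epoc")) {
  dataset <- match.arg(dataset)
  if (dataset == "speller")
    list(name = "speller", n_subjects = 35L, n_blocks = 6L, n_stimuli = 40L,
         n_channels = 9L,
         channels = c("Pz", "PO5", "PO3", "POz", "PO4", "PO6",
                      "O1", "Oz", "O2"),
         fs_hz = 250, trial_duration_s = 5,
         analysis_band_hz = c(8, 30), train_duration_s = 25)
  else
    list(name = "epoc", n_subjects = 11L, n_blocks = 20L, n_stimuli = 5L,
         n_channels = 14L, channels = NULL,
         fs_hz = 128, trial_duration_s = 5,
         stim_frequencies_hz = c(6.66, 7.50, 8.57, 10.00, 12.00),
         analysis_band_hz = c(4, 30), train_duration_s = 25)
}
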