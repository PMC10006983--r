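test_that("leave-one-block-out folds partition the trial set", {
  ts <- small_set()
  folds <- lobo_folds(ts, 10)
  expect_length(folds, ts$n_blocks)
  for (f in folds) {
    expect_identical(length(f$test), ts$n_subjects)     # one trial per subject
    blocks_te <- unique(vapply(f$test$trials, `[[`, integer(1), "block_index"))
    expect_length(blocks_te, 1L)
    blocks_tr <- vapply(f$train$trials, `[[`, integer(1), "block_index")
    expect_false(blocks_te %in% blocks_tr)
  }
  n_total <- sum(vapply(folds, function(f) length(f$test), integer(1)))
  expect_identical(n_total, length(ts))
})

test_that("incomplete designs are rejected by the fold builder", {
  ts <- small_set()
  drop_one <- ts$trials[-3]
  broken <- ssvep_trialset(drop_one, ts$n_subjects, ts$n_blocks, ts$frequencies)
  expect_error(lobo_folds(broken, 10), "incomplete design")
})

test_that("CRR is the mean per-class recall in percent", {
  expect_identical(crr(c(1, 2, 3), c(1, 2, 3), 3), 100)
  expect_identical(crr(c(1, 2, 3), c(2, 3, 1), 3), 0)
  expect_equal(crr(c(1, 1, 2, 2, 3, 3), c(1, 1, 2, 3, 3, 3), 3),
               100 * (1 + 0.5 + 1) / 3, tolerance = 1e-10)
  expect_error(crr(c(1, 1), c(1, 2), 3), "no true instances")
  expect_error(crr(integer(0), integer(0), 3), "empty")
})

test_that("usability reproduces its closed form", {
  expect_equal(usability(35, 9, 99.0238, 25, 5), 49.5119, tolerance = 1e-4)
  expect_equal(usability(11, 14, 93.3636, 25, 5), 10.8105, tolerance = 1e-4)
  expect_identical(usability(35, 9, 0, 25, 5), 0)
  expect_error(usability(35, 9, 50, -100, 5), "denominator")
  # self-consistency against a literal transcription over random draws
  set.seed(10)
  for (i in 1:1000) {
    N <- sample(2:50, 1); K <- sample(1:64, 1)
    cr <- stats::runif(1, 0, 100); tr <- stats::runif(1, 1, 100)
    te <- stats::runif(1, 0.1, 10)
    expect_equal(usability(N, K, cr, tr, te), N * cr / (tr + K * te),
                 tolerance = 1e-12)
  }
})

test_that("one-way ANOVA matches the classical decomposition", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$F, 3, tolerance = 1e-12)
  expect_identical(res$df_between, 2L)
  expect_identical(res$df_within, 6L)

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0, tolerance = 1e-12)

  big <- one_way_anova(lapply(1:3, function(i) stats::rnorm(40, mean = i)))
  expect_identical(big$df_between, 2L)
  expect_identical(big$df_within, 117L)

  degenerate <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_identical(degenerate$F, Inf)
  expect_identical(degenerate$p, 0)

  expect_error(one_way_anova(list(1:3)), ">= 2 groups")
})

test_that("post hoc pairwise comparisons are Bonferroni-corrected", {
  set.seed(4)
  g <- list(a = stats::rnorm(20), b = stats::rnorm(20, 3), c = stats::rnorm(20))
  ph <- posthoc_pairwise(g)
  expect_identical(nrow(ph), 3L)
  expect_true(all(ph$p_bonferroni >= ph$p_raw))
  expect_lt(ph$p_bonferroni[ph$group1 == "a" & ph$group2 == "b"], 0.001)
})

test_that("a uniform-random predictor lands in the CRR chance band", {
  ts_y <- rep(1:10, each = 6L)
  preds <- ssvepid:::with_seed(77L, sample(1:10, 60, replace = TRUE))
  band <- crr_chance_band(60, 10)
  observed <- crr(ts_y, preds, 10)
  expect_gte(observed, band[1])
  expect_lte(observed, band[2])
})

test_that("pooled-confusion CRR equals the mean of fold CRRs in a balanced design", {
  ts <- small_set()
  res <- run_lobo(ts, 10, bank = small_bank(), classifier = "knn")
  fold_crrs <- vapply(res$folds, `[[`, numeric(1), "crr_percent")
  expect_equal(res$crr_percent, mean(fold_crrs), tolerance = 1e-10)
  expect_identical(sum(res$confusion), length(ts))
})

test_that("a full-length window sweep matches the direct run", {
  ts <- small_set()
  direct <- run_lobo(ts, 10, bank = small_bank(), classifier = "knn")
  sw <- sweep_tw(ts, c(1, 2), bank = small_bank(), classifier = "knn")
  expect_identical(nrow(sw), 2L)
  expect_identical(sw$tw_s, c(1, 2))
  expect_equal(sw$mean_crr[2], direct$crr_percent, tolerance = 1e-10)
})
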