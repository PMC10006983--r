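test_that("spatial covariance is the trace-normalized outer product", {
  # identical rows: XX' = [[4,4],[4,4]], trace 8 -> all entries 1/4 of trace
  X <- rbind(c(1, -1, 1, -1), c(1, -1, 1, -1))
  C <- spatial_covariance(X)
  expect_equal(C, matrix(0.5, 2, 2), tolerance = 1e-15)
  expect_equal(sum(diag(C)), 1, tolerance = 1e-12)
  expect_identical(qr(C)$rank, 1L)

  tr <- small_set()$trials[[1]]
  expect_equal(sum(diag(spatial_covariance(tr))), 1, tolerance = 1e-12)

  set.seed(5)
  nt <- 4000L
  U <- matrix(stats::rnorm(2 * nt), 2)
  off <- spatial_covariance(U)[1, 2] * 2      # undo the 1/2 trace scale
  expect_lt(abs(off), 3 / sqrt(nt))

  expect_error(spatial_covariance(matrix(0, 2, 4)), "degenerate")
})

test_that("class covariance averages, shrinks, and is idempotent on duplicates", {
  tr <- small_set()$trials[[1]]
  gamma <- 1e-6
  single <- class_covariance(list(tr), gamma)
  C <- spatial_covariance(tr)
  expect_equal(single, (1 - gamma) * C + gamma * diag(nrow(C)) / nrow(C),
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(class_covariance(list(tr, tr, tr), gamma), single,
               tolerance = 1e-14)
  expect_equal(class_covariance(list(tr), gamma = 1),
               diag(nrow(C)) / nrow(C), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(class_covariance(list()), "empty")
})

test_that("the 2x2 generalized eigenproblem is solved exactly", {
  c1 <- diag(c(2, 1)) / 3
  c2 <- diag(c(1, 2)) / 3
  sol <- csp_pair(c1, c2, p = 1)
  expect_equal(sol$eigenvalues, c(2, 0.5), tolerance = 1e-12)
  # filters align with the axes, scaled so w' c2 w = 1
  expect_lt(abs(sol$W[2, 1]), 1e-12)
  expect_lt(abs(sol$W[1, 2]), 1e-12)
  expect_equal(abs(sol$W[1, 1]), sqrt(3), tolerance = 1e-12)
  expect_equal(abs(sol$W[2, 2]), sqrt(3 / 2), tolerance = 1e-12)
})

test_that("identical class covariances give a flat unit spectrum", {
  set.seed(2)
  C <- rand_spd(5)
  sol <- csp_pair(C, C, p = 2)
  expect_equal(sol$eigenvalues, rep(1, 5), tolerance = 1e-10)
})

test_that("filters satisfy the eigen-equation, the normalization, and extremality", {
  set.seed(3)
  c1 <- rand_spd(4); c2 <- rand_spd(4)
  sol <- csp_pair(c1, c2, p = 1)
  for (j in 1:2) {
    w <- sol$W[, j]
    lam <- sol$eigenvalues[if (j == 1) 1 else 4]
    expect_lt(max(abs(c1 %*% w - lam * c2 %*% w)), 1e-8)
    expect_equal(drop(t(w) %*% c2 %*% w), 1, tolerance = 1e-8)
  }
  J <- function(w) drop(t(w) %*% c1 %*% w) / drop(t(w) %*% c2 %*% w)
  V <- matrix(stats::rnorm(4 * 10000), 4)
  Jv <- colSums(V * (c1 %*% V)) / colSums(V * (c2 %*% V))
  expect_gte(J(sol$W[, 1]) + 1e-9, max(Jv))
  expect_lte(J(sol$W[, 2]) - 1e-9, min(Jv))
  expect_error(csp_pair(c1, c2, p = 3), "2\\*p")
})

test_that("one-vs-rest fitting yields the documented feature dimension", {
  cfg <- small_config(n_subjects = 3L)
  ts <- simulate_dataset(cfg)
  m <- fit_fbcsp_ovr(ts, small_bank(), p = 2)
  expect_identical(m$feature_dim, 3L * 2L * 2L * 2L)   # Np * B * 2 * p = 24
  f <- extract_features(ts$trials[[1]], m)
  expect_length(f$values, m$feature_dim)
  expect_true(all(is.finite(f$values)))
})

test_that("the two-subject problems are mirror images of each other", {
  cfg <- small_config(n_subjects = 2L, seed = 5L)
  ts <- simulate_dataset(cfg)
  m <- fit_fbcsp_ovr(ts, small_bank(), p = 2)
  unitize <- function(W) apply(W, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  for (b in 1:2) {
    W1 <- m$filters[[1]][[b]]; W2 <- m$filters[[2]][[b]]
    expect_equal(unitize(W1), unitize(W2)[, 4:1], tolerance = 1e-8)
    expect_equal(m$eigenvalues[[1]][[b]],
                 rev(1 / m$eigenvalues[[2]][[b]]), tolerance = 1e-6)
  }
})

test_that("fitting is deterministic and validates its inputs", {
  ts <- small_set()
  m1 <- fit_fbcsp_ovr(ts, small_bank(), p = 2)
  m2 <- fit_fbcsp_ovr(ts, small_bank(), p = 2)
  expect_identical(m1, m2)
  expect_error(fit_fbcsp_ovr(subset_trials(ts, subject = 1), small_bank(), 2),
               "two subjects|outside")
})

test_that("log-variance features follow the population-variance convention", {
  # hand-built model: one class, one band, identity-like filter on 1 channel
  fake <- structure(
    list(bands = filter_bank(band_spec(8, 30)), p = 1L,
         filters = list(list(matrix(1, 1, 1))), n_classes = 1L,
         n_channels = 1L, feature_dim = 1L),
    class = "csp_model")
  z1 <- matrix(c(1, -1, 1, -1), 1)            # population variance 1
  expect_equal(as.numeric(ssvepid:::features_from_banded(list(z1), fake)), 0)
  z2 <- matrix(c(2, -2, 2, -2), 1)            # population variance 4
  expect_equal(as.numeric(ssvepid:::features_from_banded(list(z2), fake)),
               log(4), tolerance = 1e-12)
  z0 <- matrix(0, 1, 4)                        # clamped at log(1e-12)
  v <- ssvepid:::features_from_banded(list(z0), fake)
  expect_true(attr(v, "clamped"))
  expect_equal(as.numeric(v), log(1e-12))
})

test_that("scaling a trial shifts every feature by exactly log(scale^2)", {
  ts <- small_set()
  m <- fit_fbcsp_ovr(ts, small_bank(), p = 2)
  tr <- ts$trials[[5]]
  f1 <- extract_features(tr, m)$values
  tr10 <- tr; tr10$data <- tr$data * 10
  f2 <- extract_features(tr10, m)$values
  expect_equal(f2 - f1, rep(log(100), length(f1)), tolerance = 1e-9)
})

test_that("trials with the wrong channel count are rejected at extraction", {
  ts <- small_set()
  m <- fit_fbcsp_ovr(ts, small_bank(), p = 2)
  bad <- ssvep_trial(matrix(stats::rnorm(2 * 250), 2), 125, 1L, 1L, 10)
  expect_error(extract_features(bad, m), "extract_features")
})

test_that("features separate subjects better between than within classes", {
  ts <- small_set()
  m <- fit_fbcsp_ovr(ts, small_bank(), p = 2)
  fm <- feature_matrix(lapply(ts$trials, extract_features, model = m))
  D <- as.matrix(stats::dist(fm$x))
  same <- outer(fm$y, fm$y, "==") & upper.tri(D)
  diff_cls <- outer(fm$y, fm$y, "!=") & upper.tri(D)
  expect_gt(mean(D[diff_cls]), mean(D[same]))
})
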