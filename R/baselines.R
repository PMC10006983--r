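#' Comparator classifier configuration
#'
#' @param svm_regularization Soft-margin cost C of the linear SVM
#'   (default 1).
#' @param knn_k Neighbour count for kNN (default 1, the canonical
#'   template-matching choice in EEG biometrics).
#' @return A `baseline_config`.
#' @export
baseline_config <- function(svm_regularization = 1.0, knn_k = 1L) {
  if (svm_regularization <= 0) stop("svm_regularization must be > 0", call. = FALSE)
  if (knn_k < 1L) stop("knn_k must be >= 1", call. = FALSE)
  structure(list(svm_regularization = svm_regularization,
                 svm_multiclass = "one-vs-rest",
                 knn_k = as.integer(knn_k), knn_metric = "euclidean"),
            class = "baseline_config")
}

#' Linear support-vector-machine comparator (one-vs-rest)
#'
#' Fits one binary linear SVM per class (that class against the pooled
#' rest) and classifies by the largest decision value. The binary
#' machines are libsvm C-classification fits with a linear kernel.
#'
#' @param x Feature matrix (samples x features), already standardized.
#' @param y Integer labels 1..C.
#' @param config A `baseline_config`.
#' @return An `svm_ovr` classifier.
#' @export
fit_linear_svm <- function(x, y, config = baseline_config()) {
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  machines <- lapply(classes, function(cls) {
    yy <- factor(ifelse(y == cls, "target", "rest"),
                 levels = c("target", "rest"))
    m <- e1071::svm(x, yy, kernel = "linear", cost = config$svm_regularization,
                    scale = FALSE, type = "C-classification")
    # libsvm orients decision values by label encounter order; normalize so
    # positive always means "target"
    dv <- as.numeric(attr(stats::predict(m, x, decision.values = TRUE),
                          "decision.values"))
    m$ovr_sign <- if (mean(dv[y == cls]) >= mean(dv[y != cls])) 1 else -1
    m
  })
  structure(list(machines = machines, classes = classes, config = config),
            class = "svm_ovr")
}

#' @export
predict.svm_ovr <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  scores <- vapply(object$machines, function(m) {
    m$ovr_sign * as.numeric(attr(stats::predict(m, x, decision.values = TRUE),
                                 "decision.values"))
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  list(labels = object$classes[max.col(scores)], scores = scores)
}

#' k-nearest-neighbour comparator
#'
#' Majority vote among the `k` Euclidean-nearest training vectors. Ties
#' are broken deterministically: smallest mean distance to the query among
#' the tied classes, then the lowest class index.
#'
#' @param x Training feature matrix (samples x features), standardized.
#' @param y Integer labels.
#' @param config A `baseline_config` (`knn_k <=` training-set size).
#' @return A `knn_classifier`.
#' @export
fit_knn <- function(x, y, config = baseline_config()) {
  if (config$knn_k > nrow(x))
    stop("knn_k exceeds the training-set size", call. = FALSE)
  structure(list(x = x, y = as.integer(y), k = config$knn_k),
            class = "knn_classifier")
}

#' @export
predict.knn_classifier <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  labels <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    d <- sqrt(colSums((t(object$x) - x[i, ])^2))
    nn <- order(d)[seq_len(object$k)]
    votes <- table(object$y[nn])
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) > 1L) {
      mean_d <- vapply(top, function(cls) mean(d[nn][object$y[nn] == cls]),
                       numeric(1))
      top <- top[mean_d == min(mean_d)]
    }
    labels[i] <- min(top)
  }
  list(labels = labels)
}
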