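#' Deep feedforward network configuration
#'
#' The classifier stacks up to three blocks, each a fully connected layer
#' followed by batch normalization and a ReLU, then a softmax classification
#' layer. The dimension schedule first expands the input into a much wider
#' representation (D1), then contracts (D2 > D3 > C), which the ablation
#' study motivates. Training uses Adam on the cross-entropy loss; the
#' returned network is the epoch snapshot with the lowest validation loss.
#'
#' @param hidden_dims Widths of blocks B1, B2, B3 (default `c(500, 100, 50)`).
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size Minibatch size (default 32; the last partial batch is
#'   kept).
#' @param epochs Hard epoch cap (default 200).
#' @param seed Seed for initialization, the validation split and batch
#'   shuffling.
#' @param validation_fraction Fraction of training trials held out,
#'   stratified by subject (default 0.2), or `"one-block"` to hold out one
#'   whole block.
#' @param blocks_kept Which blocks to keep, e.g. `c("B3")` for the ablated
#'   single-block variant.
#' @return A `dfn_config` list.
#' @export
dfn_config <- function(hidden_dims = c(500L, 100L, 50L),
                       learning_rate = 0.001, batch_size = 32L,
                       epochs = 200L, seed = 1L,
                       validation_fraction = 0.2,
                       blocks_kept = c("B1", "B2", "B3")) {
  if (length(hidden_dims) != 3L) stop("hidden_dims must have length 3", call. = FALSE)
  blocks_kept <- match.arg(blocks_kept, c("B1", "B2", "B3"), several.ok = TRUE)
  if (is.numeric(validation_fraction) &&
      (validation_fraction <= 0 || validation_fraction >= 1))
    stop("validation_fraction must lie in (0, 1)", call. = FALSE)
  structure(
    list(hidden_dims = as.integer(hidden_dims),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), seed = as.integer(seed),
         validation_fraction = validation_fraction,
         blocks_kept = blocks_kept),
    class = "dfn_config")
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Build (initialize) a deep feedforward network
#'
#' Checks the dimension schedule (`D1 > I` for the full three-block
#' architecture, strictly decreasing widths, last hidden width `> C`),
#' then draws variance-scaled fan-in (He) weights under the config seed.
#' Biases start at zero and batch-norm starts as the identity, so the
#' initial forward pass of a zero vector yields the uniform softmax.
#'
#' @param input_dim Feature dimension I.
#' @param n_classes Number of identities C.
#' @param config A `dfn_config`.
#' @return A `dfn_model`.
#' @export
build_dfn <- function(input_dim, n_classes, config = dfn_config()) {
  keep <- match(config$blocks_kept, c("B1", "B2", "B3"))
  dims <- config$hidden_dims[sort(keep)]
  if (any(diff(dims) >= 0))
    stop("invalid architecture: hidden widths must strictly decrease", call. = FALSE)
  if (dims[length(dims)] <= n_classes)
    stop("invalid architecture: last hidden width must exceed the class count",
         call. = FALSE)
  if (length(dims) == 3L && dims[1] <= input_dim)
    stop("invalid architecture: D1 must exceed the input dimension", call. = FALSE)
  layer_dims <- c(input_dim, dims, n_classes)
  nl <- length(layer_dims) - 1L               # hidden blocks + softmax layer
  with_seed(config$seed, {
    W <- vector("list", nl); b <- vector("list", nl)
    for (j in seq_len(nl)) {
      fan_in <- layer_dims[j]
      W[[j]] <- matrix(stats::rnorm(layer_dims[j + 1L] * fan_in,
                                    sd = sqrt(2 / fan_in)),
                       layer_dims[j + 1L], fan_in)
      b[[j]] <- numeric(layer_dims[j + 1L])
    }
    bn <- lapply(dims, function(d)
      list(gamma = rep(1, d), beta = numeric(d),
           run_mean = numeric(d), run_var = rep(1, d)))
    structure(
      list(W = W, b = b, bn = bn, layer_dims = layer_dims,
           n_hidden = length(dims), input_dim = as.integer(input_dim),
           class_count = as.integer(n_classes), config = config,
           trained = FALSE, format_version = "dfn-1"),
      class = "dfn_model")
  })
}

#' @export
print.dfn_model <- function(x, ...) {
  cat(sprintf("<dfn_model> %s%s, blocks %s\n",
              paste(x$layer_dims, collapse = " -> "),
              if (x$trained) " (trained)" else " (untrained)",
              paste(x$config$blocks_kept, collapse = "+")))
  invisible(x)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass. training=TRUE uses batch statistics and updates running
# stats in `model` (returned); training=FALSE uses running stats.
dfn_forward <- function(model, X, training = FALSE) {
  cache <- list(a = list(X))
  H <- X
  for (j in seq_len(model$n_hidden)) {
    Z <- H %*% t(model$W[[j]])
    Z <- sweep(Z, 2, model$b[[j]], "+")
    bn <- model$bn[[j]]
    if (training) {
      mu <- colMeans(Z)
      va <- colMeans(Z^2) - mu^2
      model$bn[[j]]$run_mean <- (1 - BN_MOMENTUM) * bn$run_mean + BN_MOMENTUM * mu
      model$bn[[j]]$run_var  <- (1 - BN_MOMENTUM) * bn$run_var + BN_MOMENTUM * va
    } else {
      mu <- bn$run_mean
      va <- bn$run_var
    }
    inv_sd <- 1 / sqrt(va + BN_EPS)
    Xhat <- sweep(sweep(Z, 2, mu, "-"), 2, inv_sd, "*")
    Y <- sweep(sweep(Xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
    H <- pmax(Y, 0)
    cache$z[[j]] <- Z; cache$xhat[[j]] <- Xhat; cache$inv_sd[[j]] <- inv_sd
    cache$mu[[j]] <- mu; cache$pre_relu[[j]] <- Y
    cache$a[[j + 1L]] <- H
  }
  jl <- model$n_hidden + 1L
  logits <- sweep(H %*% t(model$W[[jl]]), 2, model$b[[jl]], "+")
  probs <- softmax_rows(logits)
  list(probs = probs, cache = cache, model = model)
}

# Gradients of the mean cross-entropy w.r.t. all parameters.
dfn_backward <- function(model, fw, Y_onehot) {
  n <- nrow(Y_onehot)
  grads <- list(W = vector("list", model$n_hidden + 1L),
                b = vector("list", model$n_hidden + 1L),
                gamma = vector("list", model$n_hidden),
                beta = vector("list", model$n_hidden))
  jl <- model$n_hidden + 1L
  dZ <- (fw$probs - Y_onehot) / n
  grads$W[[jl]] <- crossprod(dZ, fw$cache$a[[jl]])
  grads$b[[jl]] <- colSums(dZ)
  dH <- dZ %*% model$W[[jl]]
  for (j in rev(seq_len(model$n_hidden))) {
    dY <- dH * (fw$cache$pre_relu[[j]] > 0)
    bn <- model$bn[[j]]
    Xhat <- fw$cache$xhat[[j]]
    grads$gamma[[j]] <- colSums(dY * Xhat)
    grads$beta[[j]] <- colSums(dY)
    dXhat <- sweep(dY, 2, bn$gamma, "*")
    inv_sd <- fw$cache$inv_sd[[j]]
    m <- nrow(dY)
    # batch-norm backward (population batch variance)
    s1 <- colSums(dXhat)
    s2 <- colSums(dXhat * Xhat)
    dZb <- sweep(dXhat, 2, s1 / m, "-") -
      sweep(Xhat, 2, s2 / m, "*")
    dZb <- sweep(dZb, 2, inv_sd, "*")
    grads$W[[j]] <- crossprod(dZb, fw$cache$a[[j]])
    grads$b[[j]] <- colSums(dZb)
    if (j > 1L) dH <- dZb %*% model$W[[j]]
  }
  grads
}

adam_init <- function(model) {
  zero_like <- function(x) if (is.matrix(x)) x * 0 else numeric(length(x))
  list(t = 0L,
       mW = lapply(model$W, zero_like), vW = lapply(model$W, zero_like),
       mb = lapply(model$b, zero_like), vb = lapply(model$b, zero_like),
       mg = lapply(model$bn, function(z) zero_like(z$gamma)),
       vg = lapply(model$bn, function(z) zero_like(z$gamma)),
       mB = lapply(model$bn, function(z) zero_like(z$beta)),
       vB = lapply(model$bn, function(z) zero_like(z$beta)))
}

adam_update <- function(x, g, m, v, t, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

adam_step <- function(model, grads, st, lr) {
  st$t <- st$t + 1L
  for (j in seq_along(model$W)) {
    u <- adam_update(model$W[[j]], grads$W[[j]], st$mW[[j]], st$vW[[j]], st$t, lr)
    model$W[[j]] <- u$x; st$mW[[j]] <- u$m; st$vW[[j]] <- u$v
    u <- adam_update(model$b[[j]], grads$b[[j]], st$mb[[j]], st$vb[[j]], st$t, lr)
    model$b[[j]] <- u$x; st$mb[[j]] <- u$m; st$vb[[j]] <- u$v
  }
  for (j in seq_len(model$n_hidden)) {
    u <- adam_update(model$bn[[j]]$gamma, grads$gamma[[j]], st$mg[[j]], st$vg[[j]], st$t, lr)
    model$bn[[j]]$gamma <- u$x; st$mg[[j]] <- u$m; st$vg[[j]] <- u$v
    u <- adam_update(model$bn[[j]]$beta, grads$beta[[j]], st$mB[[j]], st$vB[[j]], st$t, lr)
    model$bn[[j]]$beta <- u$x; st$mB[[j]] <- u$m; st$vB[[j]] <- u$v
  }
  list(model = model, st = st)
}

cross_entropy <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y)]
  -mean(log(pmax(p, 1e-300)))
}

# Stratified validation split: indices held out for validation.
stratified_val_split <- function(y, frac) {
  val <- integer(0)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    if (length(idx) < 2L)
      stop(sprintf("class %d has fewer than 2 training samples; cannot split", cls),
           call. = FALSE)
    n_val <- min(length(idx) - 1L, max(1L, round(frac * length(idx))))
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Train a deep feedforward network
#'
#' Minimizes the softmax cross-entropy with Adam for the configured number
#' of epochs, evaluating the validation loss after each epoch (inference
#' mode, running batch-norm statistics) and returning the parameter
#' snapshot with the lowest validation loss. Features are assumed already
#' standardized with training-fold statistics (see [fit_standardizer()]).
#'
#' @param model An untrained `dfn_model` from [build_dfn()].
#' @param x Numeric matrix, samples x features (or a list of
#'   `feature_vector` objects, in which case `y`/`blocks` are taken from
#'   them).
#' @param y Integer class labels 1..C.
#' @param blocks Optional block labels, needed for
#'   `validation_fraction = "one-block"`.
#' @return List with `model` (trained, best snapshot) and `history`
#'   (per-epoch train loss, validation loss and accuracy, and
#'   `selected_epoch`).
#' @export
train_dfn <- function(model, x, y = NULL, blocks = NULL) {
  if (is.list(x) && !is.matrix(x)) {
    fm <- feature_matrix(x)
    x <- fm$x; y <- fm$y; blocks <- fm$block
  }
  config <- model$config
  if (length(unique(y)) < 2L) stop("need at least two classes", call. = FALSE)
  if (ncol(x) != model$input_dim)
    stop("feature dimension does not match the model", call. = FALSE)
  with_seed(config$seed + 1L, {
    if (identical(config$validation_fraction, "one-block")) {
      if (is.null(blocks)) stop("one-block validation needs block labels", call. = FALSE)
      hold <- sample(unique(blocks), 1L)
      val_idx <- which(blocks == hold)
    } else {
      val_idx <- stratified_val_split(y, config$validation_fraction)
    }
    tr_idx <- setdiff(seq_along(y), val_idx)
    if (!all(sort(unique(y)) %in% y[tr_idx]))
      stop("a class is absent from the training split", call. = FALSE)
    if (!length(val_idx)) stop("empty validation split", call. = FALSE)
    x_tr <- x[tr_idx, , drop = FALSE]; y_tr <- y[tr_idx]
    x_va <- x[val_idx, , drop = FALSE]; y_va <- y[val_idx]
    C <- model$class_count
    onehot <- function(yy) {
      M <- matrix(0, length(yy), C); M[cbind(seq_along(yy), yy)] <- 1; M
    }
    st <- adam_init(model)
    n <- nrow(x_tr)
    hist <- list(train_loss = numeric(config$epochs),
                 val_loss = numeric(config$epochs),
                 val_acc = numeric(config$epochs))
    best <- list(loss = Inf, epoch = NA_integer_, model = model)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s0 in starts) {
        bi <- ord[seq(s0, min(s0 + config$batch_size - 1L, n))]
        fw <- dfn_forward(model, x_tr[bi, , drop = FALSE], training = TRUE)
        model <- fw$model                       # running BN stats updated
        ep_loss <- ep_loss + cross_entropy(fw$probs, y_tr[bi]) * length(bi)
        grads <- dfn_backward(model, fw, onehot(y_tr[bi]))
        upd <- adam_step(model, grads, st, config$learning_rate)
        model <- upd$model; st <- upd$st
      }
      hist$train_loss[ep] <- ep_loss / n
      fv <- dfn_forward(model, x_va, training = FALSE)
      vl <- cross_entropy(fv$probs, y_va)
      hist$val_loss[ep] <- vl
      hist$val_acc[ep] <- mean(max.col(fv$probs) == y_va)
      if (vl < best$loss) best <- list(loss = vl, epoch = ep, model = model)
    }
    out <- best$model
    out$trained <- TRUE
    list(model = out,
         history = list(train_loss = hist$train_loss,
                        val_loss = hist$val_loss, val_acc = hist$val_acc,
                        selected_epoch = best$epoch))
  })
}

#' Predict identities with a trained network
#'
#' Inference-mode forward pass (batch-norm running statistics); the label
#' is the argmax of the softmax probabilities.
#'
#' @param object A `dfn_model`.
#' @param x Feature matrix (samples x features), a single feature vector,
#'   or a list of `feature_vector` objects.
#' @param ... Unused.
#' @return List with `labels` (integer) and `probabilities`
#'   (samples x classes, rows summing to 1).
#' @export
predict.dfn_model <- function(object, x, ...) {
  if (is.list(x) && !is.matrix(x)) x <- feature_matrix(x)$x
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != object$input_dim)
    stop("feature dimension does not match the model", call. = FALSE)
  fw <- dfn_forward(object, x, training = FALSE)
  list(labels = max.col(fw$probs), probabilities = fw$probs)
}

#' Assemble a feature matrix from feature vectors
#'
#' @param features List of `feature_vector` objects.
#' @return List with `x` (samples x features), `y` (subject labels),
#'   `block` (block indices).
#' @export
feature_matrix <- function(features) {
  x <- do.call(rbind, lapply(features, `[[`, "values"))
  list(x = x,
       y = vapply(features, `[[`, integer(1), "subject_label"),
       block = vapply(features, `[[`, integer(1), "block_index"))
}

#' Feature standardization (z-score with training statistics)
#'
#' Per-dimension z-scoring with statistics from the training fold; applied
#' identically before the network and the distance-based baselines so the
#' comparison stays fair. Constant dimensions get unit scale.
#'
#' @param x Training feature matrix.
#' @return A `standardizer` with `mean` and `sd`.
#' @export
fit_standardizer <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  structure(list(mean = m, sd = s), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param st A `standardizer`.
#' @export
apply_standardizer <- function(st, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sweep(sweep(x, 2, st$mean, "-"), 2, st$sd, "/")
}
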