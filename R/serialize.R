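# JSON (text) model persistence. Matrices are stored as nested row arrays at
# full double precision, so save -> load round-trips are lossless and
# reruns with identical configuration produce byte-identical artifacts.

mat_to_list <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
list_to_mat <- function(l) do.call(rbind, lapply(l, as.numeric))

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = FALSE,
                       null = "null")
}

#' Save / load a fitted CSP model
#'
#' The archive holds the band edges and filter order, `p`, every spatial
#' filter matrix and eigenvalue spectrum, channel names, and a format
#' version string; loading reconstructs the model losslessly.
#'
#' @param model A `csp_model`.
#' @param path Destination file (JSON).
#' @return `save_csp_model()`: the path, invisibly; `load_csp_model()`:
#'   the restored `csp_model`.
#' @export
save_csp_model <- function(model, path) {
  obj <- list(
    format_version = model$format_version,
    bands = lapply(model$bands$bands, function(b) c(b$low_hz, b$high_hz)),
    filter_order = model$bands$order,
    p = model$p, n_classes = model$n_classes,
    n_channels = model$n_channels, channel_names = model$channel_names,
    gamma = model$gamma,
    filters = lapply(model$filters, function(cls) lapply(cls, mat_to_list)),
    eigenvalues = lapply(model$eigenvalues, function(cls) lapply(cls, unname)))
  write_json_file(obj, path)
  invisible(path)
}

#' @rdname save_csp_model
#' @export
load_csp_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  bank <- filter_bank(lapply(o$bands, function(e)
    band_spec(as.numeric(e[[1]]), as.numeric(e[[2]]))),
    order = as.integer(o$filter_order))
  filters <- lapply(o$filters, function(cls) lapply(cls, list_to_mat))
  eigenvalues <- lapply(o$eigenvalues, function(cls) lapply(cls, as.numeric))
  structure(
    list(bands = bank, p = as.integer(o$p), filters = filters,
         eigenvalues = eigenvalues, n_classes = as.integer(o$n_classes),
         n_channels = as.integer(o$n_channels),
         channel_names = as.character(unlist(o$channel_names)),
         feature_dim = as.integer(o$n_classes * length(o$bands) * 2L * o$p),
         gamma = as.numeric(o$gamma), format_version = o$format_version),
    class = "csp_model")
}

#' Save / load a trained feedforward network
#'
#' Stores the architecture (layer dimensions, blocks kept, training
#' configuration) together with all weights, biases and batch-norm state
#' as JSON.
#'
#' @param model A `dfn_model`.
#' @param path Destination file (JSON).
#' @return `save_dfn_model()`: the path, invisibly; `load_dfn_model()`:
#'   the restored `dfn_model`.
#' @export
save_dfn_model <- function(model, path) {
  cfg <- model$config
  obj <- list(
    format_version = model$format_version,
    layer_dims = model$layer_dims, n_hidden = model$n_hidden,
    input_dim = model$input_dim, class_count = model$class_count,
    trained = model$trained,
    config = list(hidden_dims = cfg$hidden_dims,
                  learning_rate = cfg$learning_rate,
                  batch_size = cfg$batch_size, epochs = cfg$epochs,
                  seed = cfg$seed,
                  validation_fraction = cfg$validation_fraction,
                  blocks_kept = cfg$blocks_kept),
    W = lapply(model$W, mat_to_list),
    b = lapply(model$b, unname),
    bn = lapply(model$bn, function(z) lapply(z, unname)))
  write_json_file(obj, path)
  invisible(path)
}

#' @rdname save_dfn_model
#' @export
load_dfn_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  vf <- o$config$validation_fraction
  cfg <- dfn_config(
    hidden_dims = as.integer(unlist(o$config$hidden_dims)),
    learning_rate = as.numeric(o$config$learning_rate),
    batch_size = as.integer(o$config$batch_size),
    epochs = as.integer(o$config$epochs), seed = as.integer(o$config$seed),
    validation_fraction = if (is.character(vf)) vf else as.numeric(vf),
    blocks_kept = as.character(unlist(o$config$blocks_kept)))
  structure(
    list(W = lapply(o$W, list_to_mat),
         b = lapply(o$b, as.numeric),
         bn = lapply(o$bn, function(z) list(
           gamma = as.numeric(unlist(z$gamma)),
           beta = as.numeric(unlist(z$beta)),
           run_mean = as.numeric(unlist(z$run_mean)),
           run_var = as.numeric(unlist(z$run_var)))),
         layer_dims = as.integer(unlist(o$layer_dims)),
         n_hidden = as.integer(o$n_hidden),
         input_dim = as.integer(o$input_dim),
         class_count = as.integer(o$class_count),
         config = cfg, trained = isTRUE(o$trained),
         format_version = o$format_version),
    class = "dfn_model")
}
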