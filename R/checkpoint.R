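# Checkpointing: the full trainable state as a single JSON document.
#
# Arrays are stored as {dim, data} with full-precision numbers, so a
# load -> save -> load round trip is bit-identical.

CHECKPOINT_FORMAT_VERSION <- 1L

serialize_tree <- function(x) {
  if (is.list(x)) {
    lapply(x, serialize_tree)
  } else {
    list(dim = dim(x) %||% length(x), data = as.numeric(x))
  }
}

deserialize_tree <- function(x) {
  if (!is.null(x$data) && !is.null(x$dim)) {
    v <- as.numeric(unlist(x$data))
    d <- as.integer(unlist(x$dim))
    if (length(d) > 1) array(v, dim = d) else v
  } else {
    lapply(x, deserialize_tree)
  }
}

#' Save a fitted model to a JSON checkpoint
#'
#' Stores the format version, the config, the signature key table and every
#' trainable array at full floating-point precision.
#'
#' @param fit A `gognn_fit`.
#' @param path Output path (.json).
#' @export
save_checkpoint <- function(fit, path) {
  doc <- list(
    format_version = CHECKPOINT_FORMAT_VERSION,
    config = unclass(fit$config),
    mode = fit$meta$mode,
    d = fit$meta$d,
    h_dim = fit$meta$h_dim,
    sig_keys = fit$meta$sig_keys,
    best_epoch = fit$best_epoch,
    message_edges = list(i = as.integer(fit$message_edges[, 1]),
                         j = as.integer(fit$message_edges[, 2])),
    theta = serialize_tree(fit$theta)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' Fails fast on version mismatch, truncation/corruption, or a dimension that
#' does not match `expect_d`.
#'
#' @param path Checkpoint path.
#' @param expect_d If given, require this embedding dimension.
#' @return A `gognn_fit` (without training history).
#' @export
load_checkpoint <- function(path, expect_d = NULL) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    abort(sprintf("corrupted checkpoint '%s': %s", path, conditionMessage(e)),
                          class = "gognn_checkpoint_error")
                  })
  if (!identical(as.integer(doc$format_version %||% -1L), CHECKPOINT_FORMAT_VERSION)) {
    abort("checkpoint format version mismatch", class = "gognn_checkpoint_error")
  }
  if (!is.null(expect_d) && !identical(as.integer(doc$d), as.integer(expect_d))) {
    abort(sprintf("checkpoint has d = %s, expected d = %d", doc$d, expect_d),
          class = "gognn_checkpoint_dim_error")
  }
  config <- do.call(gognn_config, doc$config[names(doc$config) %in% names(formals(gognn_config))])
  theta <- deserialize_tree(doc$theta)
  me <- if (length(doc$message_edges$i)) {
    cbind(as.integer(unlist(doc$message_edges$i)),
          as.integer(unlist(doc$message_edges$j)))
  } else matrix(integer(0), ncol = 2)
  meta <- list(mode = doc$mode, d = as.integer(doc$d),
               h_dim = as.integer(doc$h_dim),
               sig_keys = unlist(doc$sig_keys),
               T = config$T, L = config$L, degree_max = config$degree_max,
               activation_internal = config$activation_internal,
               activation_external = config$activation_external,
               sigma = config$sigma)
  structure(list(theta = theta, theta_final = theta, meta = meta,
                 config = config,
                 history = tibble::tibble(epoch = integer(0), loss = numeric(0),
                                          val_roc_auc = numeric(0)),
                 best_epoch = doc$best_epoch %||% NA_integer_,
                 message_edges = me, fp = NULL),
            class = "gognn_fit")
}
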