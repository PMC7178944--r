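#' Train a graph-of-graphs link prediction model
#'
#' End-to-end mini-batch training of the dual graph convolutional network (or
#' one of its ablation modes) by backpropagation with Adam. Every batch
#' recomputes the compound vectors g (internal convolution) and the refined
#' representations h (external convolution over the training-positive message
#' edges), evaluates the summed cross-entropy loss on the batch pairs, and
#' updates all trainable tensors including the atom embeddings. A fraction of
#' the training pairs is held out as a development set; the returned fit
#' carries the parameters of the epoch with the best development ROC-AUC.
#'
#' @param gog A `gog`.
#' @param split A [make_split()] object (only its `train` pairs and
#'   `message_edges` are ever touched).
#' @param config A [gognn_config()].
#' @return An object of class `gognn_fit`: fields `theta` (best parameters),
#'   `theta_final`, `meta`, `config`, `history` (tibble epoch / loss /
#'   val_roc_auc), `best_epoch`, `message_edges`.
#' @seealso [predict.gognn_fit()], [tidy.gognn_fit()], [glance.gognn_fit()]
#' @export
train_gognn <- function(gog, split, config = gognn_config()) {
  comp <- compile_gog(gog)
  n <- comp$n_graphs
  Aext <- edge_matrix_to_sparse(split$message_edges, n)
  fp <- NULL
  if (config$mode == "fingerprint") {
    fp <- fingerprint_matrix(gog, radius = config$fp_radius, nbits = config$fp_bits)
  }
  model <- init_model(gog, comp, config)
  theta <- model$theta
  meta <- model$meta
  skeleton <- theta
  flat <- flatten_params(theta)
  state <- adam_init(length(flat))

  train <- split$train
  hist_epoch <- integer(0)
  hist_loss <- numeric(0)
  hist_val <- numeric(0)
  best_val <- -Inf
  best_flat <- flat
  best_epoch <- NA_integer_

  withr::with_seed(config$seed, {
    n_tr <- nrow(train)
    n_val <- floor(config$validation_fraction * n_tr)
    idx <- sample.int(n_tr)
    val_idx <- head(idx, n_val)
    tr_idx <- idx[(n_val + 1):n_tr]
    val <- train[val_idx, , drop = FALSE]
    tr <- train[tr_idx, , drop = FALSE]
    # need both classes for a meaningful development AUC
    if (n_val > 0 && length(unique(val$label)) < 2) {
      val <- NULL
      tr <- train
    } else if (n_val == 0) {
      val <- NULL
    }

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(tr))
      epoch_loss <- 0
      for (start in seq(1, nrow(tr), by = config$batch_size)) {
        b <- ord[start:min(start + config$batch_size - 1, nrow(tr))]
        theta <- unflatten_params(flat, skeleton)
        lg <- model_loss_grad(theta, meta, comp, Aext, config,
                              tr$i[b], tr$j[b], tr$label[b],
                              train_mode = TRUE, fp = fp)
        if (!is.finite(lg$loss)) {
          abort(sprintf("training diverged: non-finite loss at epoch %d", epoch),
                class = "gognn_divergence_error")
        }
        epoch_loss <- epoch_loss + lg$loss
        st <- adam_step(flat, flatten_params(lg$grads), state, config$learning_rate)
        flat <- st$theta
        state <- st$state
      }
      val_auc <- NA_real_
      if (!is.null(val)) {
        theta <- unflatten_params(flat, skeleton)
        pv <- model_predict_pairs(theta, meta, comp, Aext, config,
                                  val$i, val$j, fp = fp)
        val_auc <- roc_auc(pv, val$label)
        if (val_auc > best_val) {
          best_val <- val_auc
          best_flat <- flat
          best_epoch <- epoch
        }
      }
      hist_epoch <- c(hist_epoch, epoch)
      hist_loss <- c(hist_loss, epoch_loss)
      hist_val <- c(hist_val, val_auc)
    }
  })
  if (!is.finite(best_val)) {
    best_flat <- flat
    best_epoch <- config$epochs
  }
  history <- tibble::tibble(epoch = hist_epoch, loss = hist_loss,
                            val_roc_auc = hist_val)
  structure(list(
    theta = unflatten_params(best_flat, skeleton),
    theta_final = unflatten_params(flat, skeleton),
    meta = meta, config = config, history = history,
    best_epoch = best_epoch, message_edges = split$message_edges,
    fp = fp
  ), class = "gognn_fit")
}

#' @export
print.gognn_fit <- function(x, ...) {
  cat(sprintf("<gognn_fit mode=%s d=%d T=%d L=%d; %d epochs, best epoch %s>\n",
              x$config$mode, x$config$d, x$config$T, x$config$L,
              nrow(x$history), x$best_epoch))
  invisible(x)
}

#' Predict link probabilities for compound pairs
#'
#' Eval-mode forward pass (no dropout) of a fitted model on a set of compound
#' pairs. Message passing uses the fit's stored training-positive edges.
#'
#' @param object A `gognn_fit`.
#' @param gog The `gog` the model was trained on.
#' @param pairs A tibble/data.frame with integer columns i, j (compound
#'   indices) or character columns id_i, id_j.
#' @param ... Unused.
#' @return A tibble id_i, id_j, score, where score is the link probability
#'   p_1.
#' @export
predict.gognn_fit <- function(object, gog, pairs, ...) {
  comp <- compile_gog(gog)
  meta <- object$meta
  if (meta$mode %in% c("dual", "internal_only")) {
    meta$sig_id <- match(comp$sig_keys, meta$sig_keys)
    if (anyNA(meta$sig_id)) {
      warn(sprintf("%d atom signature(s) unseen at training; using the fallback embedding",
                   sum(is.na(meta$sig_id))))
      meta$sig_id[is.na(meta$sig_id)] <- nrow(object$theta$embed)
    }
    meta$bucket_rows <- comp_buckets(comp, object$config$degree_max)
  }
  fp <- object$fp
  if (meta$mode == "fingerprint" && is.null(fp)) {
    fp <- fingerprint_matrix(gog, object$config$fp_radius, object$config$fp_bits)
  }
  Aext <- edge_matrix_to_sparse(object$message_edges, comp$n_graphs)
  if (!all(c("i", "j") %in% names(pairs))) {
    pairs$i <- match(pairs$id_i, gog$ids)
    pairs$j <- match(pairs$id_j, gog$ids)
  }
  p1 <- model_predict_pairs(object$theta, meta, comp, Aext, object$config,
                            pairs$i, pairs$j, fp = fp)
  tibble::tibble(id_i = gog$ids[pairs$i], id_j = gog$ids[pairs$j],
                 score = unname(p1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fit
#'
#' @param x A `gognn_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (epoch, loss, val_roc_auc).
#' @export
tidy.gognn_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `gognn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: mode, dimensions, parameter count, final and
#'   best-epoch numbers.
#' @export
glance.gognn_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode, d = x$config$d, T = x$config$T, L = x$config$L,
    n_parameters = length(flatten_params(x$theta)),
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA_real_,
    best_epoch = x$best_epoch,
    best_val_roc_auc = if (!all(is.na(x$history$val_roc_auc))) {
      max(x$history$val_roc_auc, na.rm = TRUE)
    } else NA_real_
  )
}
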