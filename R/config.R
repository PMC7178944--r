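#' Training configuration
#'
#' Hyperparameters of the dual graph convolutional network and its ablation
#' modes. Defaults follow the reference setting: Adam with learning rate
#' 0.001, dropout 0.2 after each hidden predictor layer, predictor hidden
#' sizes 128 and 64, embedding dimension selectable from \{32, 62, 128\} and
#' step counts from \{1, 3, 5\} (other values are accepted).
#'
#' @param mode One of "dual", "internal_only", "embedding_only",
#'   "fingerprint".
#' @param d Compound-vector dimension for the convolution modes.
#' @param T Internal (atom-level) convolution steps.
#' @param L External (network-level) convolution steps.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param dropout Predictor dropout rate.
#' @param hidden_sizes Two predictor hidden layer sizes.
#' @param activation_internal Internal step activation (default ReLU).
#' @param activation_external External step activation (default softmax).
#' @param sigma Final pooling activation (default softmax).
#' @param embed_init_sd Std. dev. of Gaussian embedding initialization.
#' @param embedding_dim Dimension of the free vectors in embedding_only mode
#'   (default 64).
#' @param fp_radius,fp_bits Fingerprint radius and bit width for fingerprint
#'   mode.
#' @param validation_fraction Fraction of training pairs held out per run for
#'   best-epoch selection (0 disables validation).
#' @param degree_max Top internal degree bucket.
#' @param max_atoms Load-time atom-count cap for compounds.
#' @param predictor_bias Include predictor bias vectors.
#' @param resample_negatives Redraw training negatives each epoch
#'   (default FALSE: negatives are fixed per split).
#' @param seed Integer seed covering initialization, batching and dropout.
#' @return A validated list of class `gognn_config`.
#' @export
gognn_config <- function(mode = "dual", d = 32L, T = 1L, L = 1L,
                         batch_size = 128L, learning_rate = 0.001,
                         epochs = 100L, dropout = 0.2,
                         hidden_sizes = c(128L, 64L),
                         activation_internal = "relu",
                         activation_external = "softmax",
                         sigma = "softmax",
                         embed_init_sd = 0.1, embedding_dim = 64L,
                         fp_radius = 2L, fp_bits = 2048L,
                         validation_fraction = 0.1,
                         degree_max = 5L, max_atoms = 64L,
                         predictor_bias = TRUE,
                         resample_negatives = FALSE,
                         seed = 1L) {
  mode <- match.arg(mode, c("dual", "internal_only", "embedding_only", "fingerprint"))
  if (learning_rate <= 0) abort("learning rate must be positive", class = "gognn_config_error")
  if (d < 1 || T < 0 || L < 0 || batch_size < 1 || epochs < 0) {
    abort("invalid configuration value", class = "gognn_config_error")
  }
  structure(list(
    mode = mode, d = as.integer(d), T = as.integer(T), L = as.integer(L),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    epochs = as.integer(epochs), dropout = dropout,
    hidden_sizes = as.integer(hidden_sizes),
    activation_internal = activation_internal,
    activation_external = activation_external, sigma = sigma,
    embed_init_sd = embed_init_sd, embedding_dim = as.integer(embedding_dim),
    fp_radius = as.integer(fp_radius), fp_bits = as.integer(fp_bits),
    validation_fraction = validation_fraction,
    degree_max = as.integer(degree_max), max_atoms = as.integer(max_atoms),
    predictor_bias = isTRUE(predictor_bias),
    resample_negatives = isTRUE(resample_negatives),
    seed = as.integer(seed)
  ), class = "gognn_config")
}

#' Hyperparameter grid helper
#'
#' Expands the reference model-selection grid (or any overriding choice
#' lists) into one config per row, for held-out development selection.
#'
#' @param ... Named vectors of values to cross (defaults: d in
#'   \{32, 62, 128\}, T and L in \{1, 3, 5\}, batch_size in \{64, 128, 256\}).
#' @param base A [gognn_config()] supplying every other field.
#' @return A tibble with the crossed columns and a list-column `config`.
#' @export
gognn_grid <- function(..., base = gognn_config()) {
  choices <- list(d = c(32L, 62L, 128L), T = c(1L, 3L, 5L), L = c(1L, 3L, 5L),
                  batch_size = c(64L, 128L, 256L))
  over <- list(...)
  choices[names(over)] <- over
  g <- do.call(expand.grid, c(choices, KEEP.OUT.ATTRS = FALSE))
  cfgs <- lapply(seq_len(nrow(g)), function(r) {
    cfg <- unclass(base)
    for (nm in names(g)) cfg[[nm]] <- g[[nm]][r]
    do.call(gognn_config, cfg[names(cfg) %in% names(formals(gognn_config))])
  })
  out <- tibble::as_tibble(g)
  out$config <- cfgs
  out
}
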