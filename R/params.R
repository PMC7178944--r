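# Parameter containers and initialization.
#
# All trainable arrays live in plain R lists of matrices so that a single
# generic flatten/unflatten pair (see engine.R) serves Adam updates, numeric
# gradient checks, and checkpoint serialization.

# Degree bucket: degree 0 has its own bucket; degrees 1..degree_max get one
# bucket each; anything larger shares the top bucket.
bucket_of <- function(deg, degree_max = 5L) {
  pmin(as.integer(deg), degree_max) + 1L
}

#' Trainable atom-embedding table
#'
#' One Gaussian-initialized d-vector per distinct atom signature observed in a
#' set of compounds, plus a signature-agnostic fallback row used (with a
#' warning) for signatures unseen at training time.
#'
#' @param x A `gog`, a list of `internal_graph`s, or a character vector of
#'   signature keys.
#' @param d Embedding dimension.
#' @param seed Integer seed for the Gaussian draw.
#' @param sd Per-component standard deviation of the initialization
#'   (mean 0, default 0.1).
#' @return An object of class `atom_table`: fields `d`, `keys`, and `entries`
#'   (a (length(keys)+1) x d matrix whose last row is the fallback).
#' @export
atom_table <- function(x, d, seed = 1L, sd = 0.1) {
  keys <- if (is.character(x)) {
    unique(x)
  } else {
    graphs <- if (inherits(x, "gog")) x$compounds else x
    unique(unlist(lapply(graphs, function(g) signature_key(g$atoms))))
  }
  entries <- withr::with_seed(seed, {
    matrix(rnorm((length(keys) + 1L) * d, 0, sd), ncol = d)
  })
  structure(list(d = d, keys = keys, entries = entries, seed = seed),
            class = "atom_table")
}

# Resolve atom signature keys to embedding rows; unseen keys hit the fallback.
table_lookup_ids <- function(table, keys) {
  id <- match(keys, table$keys)
  if (anyNA(id)) {
    warn(sprintf("%d atom signature(s) unseen by the embedding table; using the fallback vector",
                 sum(is.na(id))))
    id[is.na(id)] <- length(table$keys) + 1L
  }
  id
}

rand_mat <- function(nr, nc, sd) matrix(rnorm(nr * nc, 0, sd), nr, nc)

#' Internal convolution parameters
#'
#' Step- and degree-specific weight pairs (W, M) for the atom-level
#' convolution. W multiplies the receiving atom's own state, M its neighbors'
#' states; both are selected by the receiving atom's degree bucket.
#'
#' @param d State dimension.
#' @param T Number of convolution steps.
#' @param degree_max Top degree bucket (degrees above share it; degree 0 has
#'   its own bucket).
#' @param activation Step activation, `"relu"` (default), `"softmax"` or
#'   `"identity"`.
#' @param seed Seed for the Gaussian initialization (sd 1/sqrt(d)).
#' @return Object of class `internal_conv_params` with `W` and `M` as
#'   `T`-lists of bucket-lists of d x d matrices.
#' @export
internal_conv_params <- function(d, T = 1L, degree_max = 5L,
                                 activation = "relu", seed = 1L) {
  stopifnot(T >= 0, d >= 1)
  nb <- degree_max + 1L
  sdw <- 1 / sqrt(d)
  wm <- withr::with_seed(seed, {
    list(
      W = lapply(seq_len(T), function(t) lapply(seq_len(nb), function(b) rand_mat(d, d, sdw))),
      M = lapply(seq_len(T), function(t) lapply(seq_len(nb), function(b) rand_mat(d, d, sdw)))
    )
  })
  structure(list(d = d, T = as.integer(T), degree_max = as.integer(degree_max),
                 activation = activation, W = wm$W, M = wm$M),
            class = "internal_conv_params")
}

#' External convolution parameters
#'
#' Step-specific weight pairs (U, V) for the compound-level convolution.
#' No degree distinction is made at this level: external degrees are far
#' larger and more variable than atom degrees.
#'
#' @param d State dimension.
#' @param L Number of convolution steps.
#' @param f_activation Step activation (default `"softmax"`).
#' @param sigma_activation Final pooling activation (default `"softmax"`).
#' @param seed Seed for initialization.
#' @return Object of class `external_conv_params`.
#' @export
external_conv_params <- function(d, L = 1L, f_activation = "softmax",
                                 sigma_activation = "softmax", seed = 1L) {
  stopifnot(L >= 0, d >= 1)
  sdw <- 1 / sqrt(d)
  uv <- withr::with_seed(seed, {
    list(U = lapply(seq_len(L), function(l) rand_mat(d, d, sdw)),
         V = lapply(seq_len(L), function(l) rand_mat(d, d, sdw)))
  })
  structure(list(d = d, L = as.integer(L), f_activation = f_activation,
                 sigma_activation = sigma_activation, U = uv$U, V = uv$V),
            class = "external_conv_params")
}

#' Link predictor parameters
#'
#' A symmetric pairwise scorer: the pair feature (h_i + h_j) concatenated with
#' the Hadamard product (h_i * h_j) feeds a ReLU MLP with two hidden layers
#' and a 2-way softmax output (no-link, link).
#'
#' @param d_in Input width; must equal 2 x the compound-vector dimension.
#' @param hidden Integer vector of the two hidden layer sizes
#'   (default c(128, 64)).
#' @param dropout_rate Dropout rate applied after each hidden ReLU during
#'   training (default 0.2).
#' @param seed Seed for He-normal initialization.
#' @param bias Include bias vectors (default TRUE).
#' @return Object of class `predictor_params`.
#' @export
predictor_params <- function(d_in, hidden = c(128L, 64L), dropout_rate = 0.2,
                             seed = 1L, bias = TRUE) {
  stopifnot(length(hidden) == 2)
  h1 <- hidden[1]; h2 <- hidden[2]
  w <- withr::with_seed(seed, {
    list(
      W1 = rand_mat(d_in, h1, sqrt(2 / d_in)),
      W2 = rand_mat(h1, h2, sqrt(2 / h1)),
      W3 = rand_mat(h2, 2L, sqrt(2 / h2))
    )
  })
  structure(list(
    d_in = as.integer(d_in), hidden = as.integer(hidden),
    dropout_rate = dropout_rate,
    W1 = w$W1, b1 = if (bias) numeric(h1) else NULL,
    W2 = w$W2, b2 = if (bias) numeric(h2) else NULL,
    W3 = w$W3, b3 = if (bias) numeric(2L) else NULL
  ), class = "predictor_params")
}
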