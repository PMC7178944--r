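# Reference (single-graph / single-pair) forward operations.
#
# These are the readable, loop-level definitions of the dual convolution and
# the predictor. Training uses the vectorized engine (engine.R); tests assert
# the two paths agree to float tolerance.

#' One internal convolution step
#'
#' Updates every atom state: the new state of atom k is
#' f(W\[t, deg(k)\] v_k + sum over neighbors m of M\[t, deg(k)\] v_m).
#' Atoms without neighbors use only the W term.
#'
#' @param states n_atoms x d matrix of current atom states.
#' @param graph An `internal_graph`.
#' @param params [internal_conv_params()].
#' @param t Step index in 1..T.
#' @return n_atoms x d matrix of updated states.
#' @export
internal_step <- function(states, graph, params, t) {
  n <- n_atoms(graph)
  if (nrow(states) != n || ncol(states) != params$d) {
    abort("state matrix does not match graph/params dimensions",
          class = "gognn_dim_error")
  }
  if (t < 1 || t > params$T) abort("step index out of range", class = "gognn_dim_error")
  z <- matrix(0, n, params$d)
  for (k in seq_len(n)) {
    b <- bucket_of(length(graph$adjacency[[k]]), params$degree_max)
    zk <- params$W[[t]][[b]] %*% states[k, ]
    for (m in graph$adjacency[[k]]) {
      zk <- zk + params$M[[t]][[b]] %*% states[m, ]
    }
    z[k, ] <- zk
  }
  apply_act(z, params$activation)
}

#' Compound representation by internal convolution
#'
#' Runs T internal steps from the embedding-table lookup and pools:
#' g = sum over atoms k of softmax(sum over t = 0..T of v_k^(t)).
#' With per-atom softmax pooling, the components of g sum to the atom count.
#'
#' @param graph An `internal_graph`.
#' @param table An [atom_table()].
#' @param params [internal_conv_params()] with matching dimension.
#' @param sigma Pooling non-linearity (default `"softmax"`).
#' @return Numeric d-vector g.
#' @export
internal_convolve <- function(graph, table, params, sigma = "softmax") {
  if (n_atoms(graph) < 1) abort("empty graph", class = "gognn_validation_error")
  if (table$d != params$d) abort("table/params dimension mismatch", class = "gognn_dim_error")
  ids <- table_lookup_ids(table, signature_key(graph$atoms))
  v <- table$entries[ids, , drop = FALSE]
  total <- v
  for (t in seq_len(params$T)) {
    v <- internal_step(v, graph, params, t)
    total <- total + v
  }
  colSums(apply_act(total, sigma))
}

#' Refine compound vectors by external convolution
#'
#' Runs L network-level steps
#' g_i^(l+1) = f(U\[l\] g_i^(l) + sum over external neighbors m of V\[l\] g_m^(l))
#' and pools h_i = sigma(sum over l = 0..L of g_i^(l)). Isolated compounds use
#' only the U term. The adjacency used for message passing is normally the
#' training-positive edge set, not the full network, so no test link leaks
#' into representations.
#'
#' @param g_vectors n_compounds x d matrix of compound vectors g^(T).
#' @param params [external_conv_params()].
#' @param message_adjacency List of integer neighbor vectors (symmetric).
#' @return n_compounds x d matrix of final representations h.
#' @export
external_convolve <- function(g_vectors, params, message_adjacency) {
  n <- nrow(g_vectors)
  if (ncol(g_vectors) != params$d) abort("dimension mismatch", class = "gognn_dim_error")
  if (length(message_adjacency) != n) {
    abort("adjacency length != compound count", class = "gognn_dim_error")
  }
  if (n > 0 && length(unlist(message_adjacency)) &&
      (max(unlist(message_adjacency)) > n || min(unlist(message_adjacency)) < 1)) {
    abort("adjacency index out of range", class = "gognn_dim_error")
  }
  g <- g_vectors
  total <- g
  for (l in seq_len(params$L)) {
    z <- g %*% t(params$U[[l]])
    for (i in seq_len(n)) {
      nb <- message_adjacency[[i]]
      if (length(nb)) {
        z[i, ] <- z[i, ] + colSums(g[nb, , drop = FALSE] %*% t(params$V[[l]]))
      }
    }
    g <- apply_act(z, params$f_activation)
    total <- total + g
  }
  apply_act(total, params$sigma_activation)
}

#' Symmetric pair features
#'
#' Concatenates the element-wise sum and the Hadamard product of two compound
#' vectors: (h_i + h_j) then (h_i * h_j). Both blocks are symmetric in i and
#' j, so the downstream predictor is symmetric by construction.
#'
#' @param h_i,h_j Numeric vectors of equal length d.
#' @return Numeric vector of length 2d.
#' @export
pair_features <- function(h_i, h_j) {
  if (length(h_i) != length(h_j)) abort("length mismatch", class = "gognn_dim_error")
  c(h_i + h_j, h_i * h_j)
}

#' Link probability for one compound pair
#'
#' Forward pass of the predictor MLP followed by a 2-way softmax; returns
#' (p_no_link, p_link). Dropout is applied only in training mode.
#'
#' @param h_i,h_j Compound vectors of length d (d_in = 2d).
#' @param params [predictor_params()].
#' @param train_mode Apply dropout (default FALSE).
#' @return Numeric vector c(p_0, p_1) summing to 1.
#' @export
predict_link_prob <- function(h_i, h_j, params, train_mode = FALSE) {
  x <- matrix(pair_features(h_i, h_j), nrow = 1)
  fw <- predictor_forward(x, params, train_mode = train_mode)
  if (any(!is.finite(fw$P))) abort("non-finite activation in predictor", class = "gognn_numeric_error")
  drop(fw$P)
}

# Batch predictor forward with caches for backprop. X is B x 2d.
predictor_forward <- function(X, params, train_mode = FALSE) {
  add_bias <- function(Z, b) if (is.null(b)) Z else sweep(Z, 2, b, "+")
  Z1 <- add_bias(X %*% params$W1, params$b1)
  A1 <- relu(Z1)
  D1 <- NULL
  if (train_mode && params$dropout_rate > 0) {
    D1 <- matrix(rbinom(length(A1), 1, 1 - params$dropout_rate), nrow(A1)) /
      (1 - params$dropout_rate)
    A1 <- A1 * D1
  }
  Z2 <- add_bias(A1 %*% params$W2, params$b2)
  A2 <- relu(Z2)
  D2 <- NULL
  if (train_mode && params$dropout_rate > 0) {
    D2 <- matrix(rbinom(length(A2), 1, 1 - params$dropout_rate), nrow(A2)) /
      (1 - params$dropout_rate)
    A2 <- A2 * D2
  }
  Y <- add_bias(A2 %*% params$W3, params$b3)
  P <- row_softmax(Y)
  list(X = X, Z1 = Z1, A1 = A1, D1 = D1, Z2 = Z2, A2 = A2, D2 = D2, Y = Y, P = P)
}

# Backward through the predictor given dY (B x 2). Returns gradient list and dX.
predictor_backward <- function(fw, params, dY) {
  g <- list()
  g$W3 <- t(fw$A2) %*% dY
  if (!is.null(params$b3)) g$b3 <- colSums(dY)
  dA2 <- dY %*% t(params$W3)
  if (!is.null(fw$D2)) dA2 <- dA2 * fw$D2
  dZ2 <- relu_bw(fw$Z2, dA2)
  g$W2 <- t(fw$A1) %*% dZ2
  if (!is.null(params$b2)) g$b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(params$W2)
  if (!is.null(fw$D1)) dA1 <- dA1 * fw$D1
  dZ1 <- relu_bw(fw$Z1, dA1)
  g$W1 <- t(fw$X) %*% dZ1
  if (!is.null(params$b1)) g$b1 <- colSums(dZ1)
  list(grads = g, dX = dZ1 %*% t(params$W1))
}

#' Cross-entropy loss over labeled pairs
#'
#' The summed (not averaged) negative log probability of the true labels;
#' mini-batch training uses the batch sum. Probabilities of exactly zero are
#' clamped at 1e-12 with a warning.
#'
#' @param prob_pairs n x 2 matrix of (p_0, p_1) rows, or a list of length-2
#'   vectors.
#' @param labels Integer vector of 0/1 labels.
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(prob_pairs, labels) {
  if (is.list(prob_pairs)) prob_pairs <- do.call(rbind, prob_pairs)
  if (nrow(prob_pairs) != length(labels)) abort("length mismatch", class = "gognn_dim_error")
  if (!all(labels %in% c(0, 1))) abort("labels must be binary", class = "gognn_validation_error")
  p <- prob_pairs[cbind(seq_along(labels), labels + 1L)]
  if (any(p <= 0)) {
    warn("true-label probability of 0 clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  -sum(log(p))
}
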