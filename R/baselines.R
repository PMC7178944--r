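# Classical link prediction baselines: neighborhood similarity indices and
# hashed circular fingerprints.

#' Similarity-index link scores
#'
#' Scores compound pairs by a classical graph similarity index computed on a
#' given (usually training-positive) adjacency: common neighbors
#' |N(i) ∩ N(j)|, Jaccard |N(i) ∩ N(j)| / |N(i) ∪ N(j)| (0 for an empty
#' union), or the Katz index, entry (i, j) of (I - beta A)^(-1) - I, i.e. the
#' beta-damped count of paths of all lengths. Katz is computed by sparse
#' linear solves restricted to the queried columns, not by series truncation.
#'
#' @param adjacency List of integer neighbor vectors (symmetric), or a
#'   2-column index edge matrix together with `n`.
#' @param pairs Tibble/data.frame with integer columns i, j.
#' @param index One of "common_neighbors", "jaccard", "katz" (prefixes "cn"
#'   and "jc" also accepted).
#' @param beta Katz damping; must be below 1/spectral-radius of the adjacency.
#' @param n Number of nodes (required if `adjacency` is an edge matrix).
#' @return Numeric score vector aligned with `pairs` rows.
#' @export
similarity_scores <- function(adjacency, pairs, index = "common_neighbors",
                              beta = 0.001, n = NULL) {
  index <- switch(index,
    cn = "common_neighbors", common_neighbors = "common_neighbors",
    jc = "jaccard", jaccard = "jaccard",
    katz = "katz",
    abort(sprintf("unknown similarity index '%s'", index), class = "gognn_config_error"))
  if (is.list(adjacency)) {
    nbrs <- lapply(adjacency, as.integer)
    n <- length(nbrs)
  } else {
    stopifnot(!is.null(n))
    A <- edge_matrix_to_sparse(adjacency, n)
    nbrs <- lapply(seq_len(n), function(k) which(A[k, ] != 0))
  }
  if (index %in% c("common_neighbors", "jaccard")) {
    inter <- mapply(function(a, b) length(intersect(nbrs[[a]], nbrs[[b]])),
                    pairs$i, pairs$j)
    if (index == "common_neighbors") return(as.numeric(inter))
    uni <- mapply(function(a, b) length(union(nbrs[[a]], nbrs[[b]])),
                  pairs$i, pairs$j)
    sc <- ifelse(uni == 0, 0, inter / uni)
    return(as.numeric(sc))
  }
  # Katz
  e <- do.call(rbind, lapply(seq_len(n), function(k) {
    nb <- nbrs[[k]]; nb <- nb[nb > k]
    if (length(nb)) cbind(k, nb) else NULL
  }))
  A <- edge_matrix_to_sparse(if (is.null(e)) matrix(integer(0), ncol = 2) else e, n)
  if (length(A@x)) {
    # power iteration bound on the spectral radius
    v <- rep(1 / sqrt(n), n)
    for (it in 1:50) {
      w <- as.numeric(A %*% v)
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      v <- w / nw
    }
    rho <- if (exists("nw") && nw > 0) nw else 0
    if (rho > 0 && beta >= 1 / rho) {
      abort(sprintf("beta = %g is not below 1/spectral-radius (~%g); Katz series diverges",
                    beta, 1 / rho), class = "gognn_katz_beta_error")
    }
  }
  Msys <- Matrix::Diagonal(n) - beta * A
  cols <- sort(unique(pairs$j))
  rhs <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1, dims = c(n, length(cols)))
  sol <- as.matrix(Matrix::solve(Msys, rhs))
  K <- sol - as.matrix(rhs)   # (I - beta A)^{-1} - I, queried columns
  K[cbind(pairs$i, match(pairs$j, cols))]
}

# ---- hashed circular fingerprints ----

# Deterministic polynomial hash over non-negative integers, mod the Mersenne
# prime 2^31 - 1. All intermediates stay below 2^53, so the arithmetic is
# exact in doubles and stable across platforms.
hash_ints <- function(x) {
  p <- 2147483647
  h <- 17
  for (v in x) {
    h <- (h * 131 + (v %% p)) %% p
  }
  # final scramble with small multipliers (kept exact in doubles)
  h <- (h * 31 + 7) %% p
  h
}

atom_init_hash <- function(atoms) {
  elem_code <- vapply(atoms$element, function(e) sum(utf8ToInt(e) * (256^(seq_along(utf8ToInt(e)) - 1))), numeric(1))
  vapply(seq_len(nrow(atoms)), function(k) {
    hash_ints(c(elem_code[k], atoms$valence[k], atoms$hydrogen_count[k],
                atoms$degree[k], as.integer(atoms$aromatic[k])))
  }, numeric(1))
}

#' Hashed circular (Morgan-style) fingerprint
#'
#' Iterative neighborhood hashing: every atom starts from a hash of its
#' signature; each round combines an atom's hash with the sorted hashes of
#' its neighbors; every (atom, round) environment identifier is folded into
#' an nbits-wide binary vector. Deterministic across runs and platforms, and
#' invariant under atom relabeling.
#'
#' @param graph An `internal_graph`.
#' @param radius Number of hashing rounds (default 2, ECFP4-like).
#' @param nbits Fingerprint width (default 2048).
#' @return Object of class `fingerprint`: fields `bits` (integer 0/1 vector),
#'   `radius`, `nbits`.
#' @export
morgan_fingerprint <- function(graph, radius = 2L, nbits = 2048L) {
  h <- atom_init_hash(graph$atoms)
  idents <- h
  for (r in seq_len(radius)) {
    h <- vapply(seq_along(h), function(k) {
      nb <- graph$adjacency[[k]]
      hash_ints(c(r, h[k], sort(h[nb])))
    }, numeric(1))
    idents <- c(idents, h)
  }
  bits <- integer(nbits)
  bits[(idents %% nbits) + 1] <- 1L
  structure(list(bits = bits, radius = as.integer(radius), nbits = as.integer(nbits)),
            class = "fingerprint")
}

#' Fingerprint feature matrix for a GoG
#'
#' Stacks every compound's hashed fingerprint into an n_compounds x nbits
#' 0/1 matrix: the frozen (zero-gradient) stand-in for the learned compound
#' representation in fingerprint mode.
#'
#' @param gog A `gog`.
#' @param radius,nbits Fingerprint parameters.
#' @return Numeric matrix (n_compounds x nbits).
#' @export
fingerprint_matrix <- function(gog, radius = 2L, nbits = 2048L) {
  t(vapply(gog$compounds,
           function(g) as.numeric(morgan_fingerprint(g, radius, nbits)$bits),
           numeric(nbits)))
}

#' Baseline link scores for a set of pairs
#'
#' Convenience wrapper: similarity-index scores on the training-positive
#' adjacency (scoring with test edges present would leak labels).
#'
#' @param gog A `gog` (ids only).
#' @param message_edges 2-column index matrix of training-positive edges.
#' @param pairs Pairs tibble with i, j.
#' @param index Similarity index name.
#' @param beta Katz damping.
#' @return Tibble id_i, id_j, score.
#' @export
baseline_scores <- function(gog, message_edges, pairs, index = "katz", beta = 0.001) {
  n <- length(gog$compounds)
  sc <- similarity_scores(message_edges, pairs, index = index, beta = beta, n = n)
  tibble::tibble(id_i = gog$ids[pairs$i], id_j = gog$ids[pairs$j], score = sc)
}
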