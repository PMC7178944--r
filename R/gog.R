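#' Atom signature
#'
#' The discrete label that keys the trainable initial atom embedding: element,
#' valence, hydrogen count, degree, and aromaticity. Two atoms with identical
#' field values share one signature (and hence one embedding vector).
#'
#' @param element Element symbol (character scalar, e.g. "C").
#' @param valence Non-negative integer valence.
#' @param hydrogen_count Non-negative integer number of attached hydrogens
#'   (hydrogens are not explicit atoms).
#' @param degree Non-negative integer heavy-atom degree; must equal the length
#'   of the atom's adjacency list in its graph.
#' @param aromatic Logical aromaticity flag.
#' @return A one-row data.frame with the five signature fields.
#' @export
atom_signature <- function(element, valence, hydrogen_count, degree, aromatic = FALSE) {
  stopifnot(is.character(element), valence >= 0, hydrogen_count >= 0, degree >= 0)
  data.frame(
    element = element,
    valence = as.integer(valence),
    hydrogen_count = as.integer(hydrogen_count),
    degree = as.integer(degree),
    aromatic = as.logical(aromatic),
    stringsAsFactors = FALSE
  )
}

# Canonical string key of each row of an atoms data.frame.
signature_key <- function(atoms) {
  paste(atoms$element, atoms$valence, atoms$hydrogen_count, atoms$degree,
        as.integer(atoms$aromatic), sep = ":")
}

#' Molecular (internal) graph
#'
#' A compound as a labeled undirected graph: atoms carry signatures, bonds are
#' unlabeled edges (bond types are deliberately dropped). The degree field of
#' each signature is derived from the bond list, never taken on trust.
#'
#' @param id Compound identifier (character scalar).
#' @param atoms Data frame with columns element, valence, hydrogen_count,
#'   aromatic (a degree column, if present, is recomputed).
#' @param bonds Two-column integer matrix of 1-based atom index pairs, or NULL
#'   for a bond-less molecule.
#' @return An object of class `internal_graph` with fields `id`, `atoms`
#'   (including the derived degree column) and `adjacency` (list of integer
#'   neighbor vectors).
#' @export
internal_graph <- function(id, atoms, bonds = NULL) {
  n <- nrow(atoms)
  if (is.null(n) || n < 1) {
    abort("internal graph needs at least one atom", class = "gognn_validation_error")
  }
  adj <- rep(list(integer(0)), n)
  if (!is.null(bonds) && NROW(bonds) > 0) {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2)
    if (any(bonds < 1 | bonds > n)) {
      abort(sprintf("bond atom index out of range in compound '%s'", id),
            class = "gognn_validation_error")
    }
    if (any(bonds[, 1] == bonds[, 2])) {
      abort(sprintf("self-bond in compound '%s'", id), class = "gognn_validation_error")
    }
    # symmetrize + dedupe
    key <- pair_key(bonds[, 1], bonds[, 2], n)
    keep <- !duplicated(key)
    b <- bonds[keep, , drop = FALSE]
    lo <- pmin(b[, 1], b[, 2]); hi <- pmax(b[, 1], b[, 2])
    adj <- lapply(seq_len(n), function(k) sort(c(hi[lo == k], lo[hi == k])))
  }
  atoms$degree <- as.integer(lengths(adj))
  atoms$aromatic <- as.logical(atoms$aromatic)
  structure(
    list(id = as.character(id), atoms = atoms, adjacency = adj),
    class = "internal_graph"
  )
}

#' @export
print.internal_graph <- function(x, ...) {
  cat(sprintf("<internal_graph '%s': %d atoms, %d bonds>\n",
              x$id, nrow(x$atoms), sum(lengths(x$adjacency)) / 2))
  invisible(x)
}

n_atoms <- function(g) nrow(g$atoms)

internal_edge_matrix <- function(g) {
  n <- n_atoms(g)
  pairs <- do.call(rbind, lapply(seq_len(n), function(k) {
    nb <- g$adjacency[[k]]
    nb <- nb[nb > k]
    if (length(nb)) cbind(k, nb) else NULL
  }))
  if (is.null(pairs)) matrix(integer(0), ncol = 2) else pairs
}

#' Build and validate a graph of graphs
#'
#' Assembles compounds (internal graphs) and an external edge list over their
#' ids into a validated two-level graph of graphs. Edges are symmetrized and
#' deduplicated; endpoints must name existing compounds; self-loops and
#' duplicate compound ids are rejected with distinct error classes.
#'
#' @param compounds List of [internal_graph()] objects with unique ids.
#' @param edges Two-column character matrix / data.frame of compound id pairs
#'   (may be empty).
#' @return An object of class `gog` with fields `compounds`, `ids`, and
#'   `external_adjacency` (list of integer neighbor index vectors, 1-based).
#' @export
build_gog <- function(compounds, edges = NULL) {
  ids <- vapply(compounds, function(g) g$id, character(1))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate compound id '%s'", ids[duplicated(ids)][1]),
          class = "gognn_duplicate_id_error")
  }
  n <- length(compounds)
  adj <- rep(list(integer(0)), n)
  if (!is.null(edges) && NROW(edges) > 0) {
    e <- as.matrix(edges)[, 1:2, drop = FALSE]
    i <- match(e[, 1], ids)
    j <- match(e[, 2], ids)
    if (anyNA(i) || anyNA(j)) {
      bad <- c(e[, 1][is.na(i)], e[, 2][is.na(j)])[1]
      abort(sprintf("edge references unknown compound id '%s'", bad),
            class = "gognn_unknown_id_error")
    }
    if (any(i == j)) {
      abort(sprintf("self-loop edge on compound '%s'", e[i == j, 1][1]),
            class = "gognn_self_loop_error")
    }
    key <- pair_key(i, j, n)
    keep <- !duplicated(key)
    lo <- pmin(i, j)[keep]; hi <- pmax(i, j)[keep]
    adj <- lapply(seq_len(n), function(k) sort(c(hi[lo == k], lo[hi == k])))
  }
  structure(
    list(compounds = compounds, ids = ids, external_adjacency = adj),
    class = "gog"
  )
}

#' @export
print.gog <- function(x, ...) {
  cat(sprintf("<gog: %d compounds, %d external edges>\n",
              length(x$compounds), n_external_edges(x)))
  invisible(x)
}

n_external_edges <- function(gog) sum(lengths(gog$external_adjacency)) / 2

# External edge list as a 2-column integer matrix (i < j).
external_edge_matrix <- function(gog) {
  n <- length(gog$compounds)
  pairs <- do.call(rbind, lapply(seq_len(n), function(k) {
    nb <- gog$external_adjacency[[k]]
    nb <- nb[nb > k]
    if (length(nb)) cbind(k, nb) else NULL
  }))
  if (is.null(pairs)) matrix(integer(0), ncol = 2) else pairs
}

# Sparse symmetric adjacency over compounds from a 2-column index matrix.
edge_matrix_to_sparse <- function(edges, n) {
  if (NROW(edges) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  }
  Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
    x = 1, dims = c(n, n)
  )
}

#' Summary statistics of a graph of graphs
#'
#' Counts, link density over all unordered compound pairs, mean internal graph
#' size, mean external degree, and the external degree histogram.
#'
#' @param gog A [build_gog()] object with at least two compounds.
#' @return A one-row tibble with columns `n_compounds`, `n_edges`, `n_pairs`,
#'   `density`, `mean_internal_size`, `mean_external_degree`, and a
#'   list-column `degree_histogram` (named counts, degree -> number of
#'   compounds). `n_pairs` and `density` are exact at full precision.
#' @examples
#' g <- lapply(1:4, function(k) internal_graph(paste0("c", k),
#'   atom_signature("C", 4, 4, 0)))
#' gg <- build_gog(g, cbind(c("c1", "c2"), c("c2", "c3")))
#' gog_stats(gg)
#' @export
gog_stats <- function(gog) {
  n <- length(gog$compounds)
  if (n < 2) {
    abort("link density is undefined for fewer than 2 compounds",
          class = "gognn_undefined_density_error")
  }
  deg <- lengths(gog$external_adjacency)
  m <- sum(deg) / 2
  n_pairs <- n * (n - 1) / 2
  hist <- table(factor(deg, levels = sort(unique(deg))))
  tibble::tibble(
    n_compounds = n,
    n_edges = m,
    n_pairs = n_pairs,
    density = m / n_pairs,
    mean_internal_size = mean(vapply(gog$compounds, n_atoms, numeric(1))),
    mean_external_degree = mean(deg),
    degree_histogram = list(setNames(as.integer(hist), names(hist)))
  )
}
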