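# Synthetic graph-of-graphs benchmark generator.
#
# Links are planted to depend on BOTH levels of structure: an internal
# 3-atom labeled triangle motif (carried by a controllable fraction of
# compounds) multiplies the link probability when both endpoints carry it,
# and external block structure (communities with within/between link factors)
# shapes the network. Density and degree-tail weight are controlled
# directly, emulating networks of different sparsity and tail behavior.

#' Synthetic GoG specification
#'
#' @param n_compounds Number of compounds.
#' @param atom_alphabet Element symbols for random atoms (default C, N, O, S).
#' @param size_range Atom-count range per compound (default 8..24; cap 64).
#' @param motif_fraction Probability a compound carries the planted
#'   sulfur-triangle motif.
#' @param n_communities Number of external communities K.
#' @param community_weights Community sampling weights (default uniform).
#' @param p_in,p_out Relative within/between-community link factors.
#' @param motif_boost Multiplier on the link probability when both endpoints
#'   carry the motif (1 = no internal signal).
#' @param degree_model "bernoulli" (light-tailed, independent pairs) or
#'   "powerlaw" (heavy-tailed expected degrees, Chung-Lu style).
#' @param powerlaw_gamma Tail exponent of the expected-degree distribution.
#' @param target_density Expected link density over all pairs.
#' @param seed Integer seed.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 300L,
                           atom_alphabet = c("C", "N", "O", "S"),
                           size_range = c(8L, 24L),
                           motif_fraction = 0.5,
                           n_communities = 3L,
                           community_weights = NULL,
                           p_in = 1, p_out = 1,
                           motif_boost = 1,
                           degree_model = c("bernoulli", "powerlaw"),
                           powerlaw_gamma = 2.5,
                           target_density = 0.05,
                           seed = 1L) {
  degree_model <- match.arg(degree_model)
  if (target_density <= 0 || target_density >= 1) {
    abort("target density must be in (0, 1)", class = "gognn_config_error")
  }
  if (motif_fraction < 0 || motif_fraction > 1) {
    abort("motif fraction must be a probability", class = "gognn_config_error")
  }
  if (size_range[2] > 64L) abort("compound size cap is 64 atoms", class = "gognn_config_error")
  if (is.null(community_weights)) community_weights <- rep(1, n_communities)
  structure(list(
    n_compounds = as.integer(n_compounds), atom_alphabet = atom_alphabet,
    size_range = as.integer(size_range), motif_fraction = motif_fraction,
    n_communities = as.integer(n_communities),
    community_weights = community_weights / sum(community_weights),
    p_in = p_in, p_out = p_out, motif_boost = motif_boost,
    degree_model = degree_model, powerlaw_gamma = powerlaw_gamma,
    target_density = target_density, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

typical_valence <- function(element) {
  v <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, F = 1L, Cl = 1L, Br = 1L)
  out <- v[element]
  out[is.na(out)] <- 4L
  unname(out)
}

# Would adding bond (a, b) close a triangle whose three atoms are all "S"?
closes_s_triangle <- function(adj, elements, a, b) {
  if (elements[a] != "S" || elements[b] != "S") return(FALSE)
  common <- intersect(adj[[a]], adj[[b]])
  any(elements[common] == "S")
}

#' Generate one random molecule
#'
#' A random connected labeled graph: a random spanning tree plus extra bonds,
#' all under a degree cap of 4 (an organic valence limit). Motif-bearing
#' compounds contain the planted triangle of three mutually bonded sulfur
#' atoms; non-motif compounds are guaranteed not to contain it (candidate
#' extra bonds that would close an all-sulfur triangle are skipped).
#' Signature degree fields are derived from the final adjacency. Uses the
#' current RNG state; seed at the call site.
#'
#' @param spec A [synthetic_spec()].
#' @param id Compound identifier.
#' @param motif Plant the motif in this compound?
#' @return An `internal_graph`.
#' @export
gen_internal_graph <- function(spec, id = "c1", motif = FALSE) {
  n <- sample(spec$size_range[1]:spec$size_range[2], 1)
  if (motif) n <- max(n, 3L)
  elements <- sample(spec$atom_alphabet, n, replace = TRUE)
  adj <- rep(list(integer(0)), n)
  deg <- integer(n)
  add_bond <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
    deg[a] <<- deg[a] + 1L
    deg[b] <<- deg[b] + 1L
  }
  start <- 1L
  if (motif) {
    elements[1:3] <- "S"
    add_bond(1L, 2L); add_bond(2L, 3L); add_bond(1L, 3L)
    start <- 4L
  } else if (n >= 2) {
    start <- 2L
  }
  if (start <= n) {
    for (k in start:n) {
      pool <- which(deg[seq_len(k - 1)] < 4L)
      anchor <- if (length(pool) == 1) pool else sample(pool, 1)
      add_bond(k, anchor)
    }
  }
  # extra bonds (sparse cycles), respecting the degree cap
  n_extra <- rbinom(1, n, 0.25)
  for (e in seq_len(n_extra)) {
    cand <- which(deg < 4L)
    if (length(cand) < 2) break
    ab <- sample(cand, 2)
    a <- ab[1]; b <- ab[2]
    if (b %in% adj[[a]]) next
    if (!motif && closes_s_triangle(adj, elements, a, b)) next
    add_bond(a, b)
  }
  val <- pmax(typical_valence(elements), deg)
  atoms <- data.frame(
    element = elements,
    valence = as.integer(val),
    hydrogen_count = as.integer(pmax(0L, val - deg)),
    aromatic = FALSE,
    stringsAsFactors = FALSE
  )
  bonds <- do.call(rbind, lapply(seq_len(n), function(k) {
    nb <- adj[[k]]; nb <- nb[nb > k]
    if (length(nb)) cbind(k, nb) else NULL
  }))
  internal_graph(id, atoms, bonds)
}

# TRUE if the compound contains three mutually bonded sulfur atoms
# (exhaustive search over sulfur triples' adjacency).
has_motif <- function(graph) {
  s <- which(graph$atoms$element == "S")
  if (length(s) < 3) return(FALSE)
  for (a in s) {
    nb <- intersect(graph$adjacency[[a]], s)
    nb <- nb[nb > a]
    for (b in nb) {
      if (length(intersect(intersect(graph$adjacency[[a]], graph$adjacency[[b]]), s[s > b]))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Generate a synthetic graph of graphs with ground truth
#'
#' Draws communities and motif flags, generates molecules, and places
#' external links. In bernoulli mode every pair is linked independently with
#' probability proportional to the community factor (p_in within, p_out
#' between) times the motif boost (when both endpoints carry the motif),
#' rescaled so the expected density equals `target_density`. In powerlaw
#' mode each compound additionally receives an expected-degree weight drawn
#' from a discrete power law with exponent `powerlaw_gamma` (truncated at
#' n - 1), and pair probabilities are further proportional to the weight
#' product (Chung-Lu style), giving a heavy-tailed degree distribution.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `gog` (a validated `gog`) and `truth`, a tibble with
#'   per-compound id, community, motif flag and degree weight.
#' @export
gen_gog <- function(spec) {
  n <- spec$n_compounds
  if (n < 2) abort("need at least 2 compounds", class = "gognn_config_error")
  withr::with_seed(spec$seed, {
    community <- sample.int(spec$n_communities, n, replace = TRUE,
                            prob = spec$community_weights)
    motif <- runif(n) < spec$motif_fraction
    compounds <- lapply(seq_len(n), function(k) {
      gen_internal_graph(spec, id = sprintf("c%04d", k), motif = motif[k])
    })
    w <- rep(1, n)
    if (spec$degree_model == "powerlaw") {
      u <- runif(n)
      w <- floor((1 - u)^(-1 / (spec$powerlaw_gamma - 1)))
      w <- pmin(pmax(w, 1), n - 1)
    }
    # upper-triangle pair index
    i <- rep.int(seq_len(n - 1), (n - 1):1)
    j <- sequence((n - 1):1, from = 2:n)
    fac <- ifelse(community[i] == community[j], spec$p_in, spec$p_out)
    fac <- fac * ifelse(motif[i] & motif[j], spec$motif_boost, 1)
    fac <- fac * w[i] * w[j]
    # solve sum(pmin(c * fac, 1)) = target * n_pairs for c; plain
    # proportional rescaling undershoots when heavy-tailed factors clip at 1
    want <- spec$target_density * length(fac)
    lo <- 0
    hi <- want / sum(fac) * 2 + 1e-12
    while (sum(pmin(hi * fac, 1)) < want && hi < 1e12) hi <- hi * 2
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (sum(pmin(mid * fac, 1)) < want) lo <- mid else hi <- mid
    }
    p <- pmin((lo + hi) / 2 * fac, 1)
    linked <- rbinom(length(p), 1, p) == 1
    edges <- cbind(i[linked], j[linked])
  })
  ids <- vapply(compounds, function(g) g$id, character(1))
  gog <- build_gog(compounds, cbind(ids[edges[, 1]], ids[edges[, 2]]))
  truth <- tibble::tibble(
    id = ids, community = as.integer(community), motif = motif,
    degree_weight = as.numeric(w)
  )
  list(gog = gog, truth = truth)
}
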