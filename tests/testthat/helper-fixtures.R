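# Shared fixtures, built in code.

# A one-atom carbon compound.
carbon_atom <- function(id = "c") {
  internal_graph(id, atom_signature("C", 4, 4, 0))
}

# A small hand-built molecule: a 3-atom path C-O-C.
path3_graph <- function(id = "p3") {
  atoms <- rbind(atom_signature("C", 4, 3, 1), atom_signature("O", 2, 0, 2),
                 atom_signature("C", 4, 3, 1))
  internal_graph(id, atoms, cbind(c(1, 2), c(2, 3)))
}

# A 4-atom star: central C bonded to three neighbors.
star4_graph <- function(id = "s4") {
  atoms <- rbind(atom_signature("C", 4, 1, 3), atom_signature("O", 2, 1, 1),
                 atom_signature("N", 3, 2, 1), atom_signature("C", 4, 3, 1))
  internal_graph(id, atoms, cbind(c(1, 1, 1), c(2, 3, 4)))
}

# A GoG of k single-atom compounds with the given id-pair edges.
tiny_gog <- function(k = 3, edges = NULL) {
  comps <- lapply(seq_len(k), function(i) carbon_atom(paste0("c", i)))
  build_gog(comps, edges)
}

# Small random synthetic GoG for pipeline tests.
toy_gog <- function(n = 20, density = 0.2, seed = 1, size_range = c(4L, 8L), ...) {
  gen_gog(synthetic_spec(n_compounds = n, target_density = density,
                         size_range = size_range, seed = seed, ...))
}

# A GoG with n single-atom compounds and exactly m distinct random edges.
# Used to recompute published pair-count / density arithmetic from real code.
random_edge_gog <- function(n, m, seed = 1) {
  comps <- lapply(seq_len(n), function(i) carbon_atom(sprintf("c%06d", i)))
  withr::with_seed(seed, {
    r <- sample(n * (n - 1) / 2, m)
  })
  ij <- gognn:::pair_rank_to_ij(r, n)
  build_gog(comps, cbind(sprintf("c%06d", ij[, 1]), sprintf("c%06d", ij[, 2])))
}

# Straight-line reimplementation of the internal convolution step
# (independent loops; the oracle for Eq.-style updates).
oracle_internal_states <- function(graph, v0, params) {
  states <- list(v0)
  v <- v0
  for (t in seq_len(params$T)) {
    nv <- v * 0
    for (k in seq_len(nrow(v))) {
      b <- min(length(graph$adjacency[[k]]), params$degree_max) + 1
      z <- as.numeric(params$W[[t]][[b]] %*% v[k, ])
      for (m in graph$adjacency[[k]]) {
        z <- z + as.numeric(params$M[[t]][[b]] %*% v[m, ])
      }
      if (params$activation == "relu") z <- pmax(z, 0)
      if (params$activation == "softmax") z <- exp(z - max(z)) / sum(exp(z - max(z)))
      nv[k, ] <- z
    }
    v <- nv
    states[[t + 1]] <- v
  }
  states
}

oracle_internal_g <- function(graph, v0, params) {
  states <- oracle_internal_states(graph, v0, params)
  su <- Reduce(`+`, states)
  out <- numeric(ncol(v0))
  for (k in seq_len(nrow(v0))) {
    e <- exp(su[k, ] - max(su[k, ]))
    out <- out + e / sum(e)
  }
  out
}

# Straight-line oracle of the external convolution.
oracle_external_h <- function(adj, g, params) {
  gs <- list(g)
  cur <- g
  act <- function(z, name) {
    if (name == "relu") return(pmax(z, 0))
    if (name == "softmax") return(exp(z - max(z)) / sum(exp(z - max(z))))
    z
  }
  for (l in seq_len(params$L)) {
    nxt <- cur * 0
    for (i in seq_len(nrow(cur))) {
      z <- as.numeric(params$U[[l]] %*% cur[i, ])
      for (m in adj[[i]]) z <- z + as.numeric(params$V[[l]] %*% cur[m, ])
      nxt[i, ] <- act(z, params$f_activation)
    }
    cur <- nxt
    gs[[l + 1]] <- cur
  }
  su <- Reduce(`+`, gs)
  t(apply(su, 1, act, name = params$sigma_activation))
}

# Straight-line oracle of the predictor forward pass (eval mode).
oracle_predict <- function(h_i, h_j, p) {
  x <- c(h_i + h_j, h_i * h_j)
  a1 <- pmax(as.numeric(x %*% p$W1) + (p$b1 %||% 0), 0)
  a2 <- pmax(as.numeric(a1 %*% p$W2) + (p$b2 %||% 0), 0)
  y <- as.numeric(a2 %*% p$W3) + (p$b3 %||% 0)
  exp(y - max(y)) / sum(exp(y - max(y)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Central-difference gradient of the batch loss over every trainable scalar.
numeric_grad <- function(theta, meta, comp, Aext, cfg, pi, pj, lab, h = 1e-5,
                         fp = NULL) {
  flat <- gognn:::flatten_params(theta)
  num <- numeric(length(flat))
  for (k in seq_along(flat)) {
    up <- flat; up[k] <- up[k] + h
    dn <- flat; dn[k] <- dn[k] - h
    lp <- gognn:::model_loss_grad(gognn:::unflatten_params(up, theta), meta, comp,
                                  Aext, cfg, pi, pj, lab, train_mode = FALSE,
                                  fp = fp, want_grad = FALSE)$loss
    lm <- gognn:::model_loss_grad(gognn:::unflatten_params(dn, theta), meta, comp,
                                  Aext, cfg, pi, pj, lab, train_mode = FALSE,
                                  fp = fp, want_grad = FALSE)$loss
    num[k] <- (lp - lm) / (2 * h)
  }
  num
}
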