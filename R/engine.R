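# Vectorized training engine.
#
# All compounds' atoms are stacked into one block: a single sparse
# block-diagonal adjacency carries every molecule's bonds, so an internal
# convolution step is a handful of sparse products plus one dense product per
# degree bucket, instead of a loop over molecules. The external convolution
# operates on the n_compounds x d matrix with the (sparse) message adjacency.
# Backward passes mirror the forward caches exactly; tests check them against
# central finite differences.

# Precompile a GoG into the stacked-atom representation.
compile_gog <- function(gog) {
  n_g <- length(gog$compounds)
  sizes <- vapply(gog$compounds, n_atoms, numeric(1))
  offsets <- c(0, cumsum(sizes))
  nat <- offsets[n_g + 1]
  keys <- unlist(lapply(gog$compounds, function(g) signature_key(g$atoms)))
  graph_index <- rep.int(seq_len(n_g), sizes)
  deg <- unlist(lapply(gog$compounds, function(g) lengths(g$adjacency)))
  # stacked bond adjacency
  ii <- unlist(lapply(seq_len(n_g), function(k) {
    g <- gog$compounds[[k]]
    rep.int(seq_len(n_atoms(g)), lengths(g$adjacency)) + offsets[k]
  }))
  jj <- unlist(lapply(seq_len(n_g), function(k) {
    unlist(gog$compounds[[k]]$adjacency) + offsets[k]
  }))
  Aint <- Matrix::sparseMatrix(i = as.integer(ii %||% integer(0)),
                               j = as.integer(jj %||% integer(0)),
                               x = 1, dims = c(nat, nat))
  list(n_graphs = n_g, n_atoms = nat, sizes = sizes, offsets = offsets,
       sig_keys = keys, graph_index = graph_index, degree = deg, Aint = Aint)
}

comp_buckets <- function(comp, degree_max) {
  bucket <- bucket_of(comp$degree, degree_max)
  lapply(seq_len(degree_max + 1L), function(b) which(bucket == b))
}

# ---- stacked internal convolution ----

internal_forward_stacked <- function(theta, comp, bucket_rows, act, T, sig_id) {
  d <- ncol(theta$embed)
  states <- vector("list", T + 1L)
  states[[1L]] <- theta$embed[sig_id, , drop = FALSE]
  Zs <- vector("list", T)
  Ss <- vector("list", T)
  for (t in seq_len(T)) {
    S <- as.matrix(comp$Aint %*% states[[t]])
    Z <- matrix(0, comp$n_atoms, d)
    for (b in seq_along(bucket_rows)) {
      r <- bucket_rows[[b]]
      if (!length(r)) next
      Z[r, ] <- states[[t]][r, , drop = FALSE] %*% t(theta$W[[t]][[b]]) +
        S[r, , drop = FALSE] %*% t(theta$M[[t]][[b]])
    }
    states[[t + 1L]] <- apply_act(Z, act)
    Zs[[t]] <- Z
    Ss[[t]] <- S
  }
  SU <- Reduce(`+`, states)
  A <- row_softmax(SU)
  g <- rowsum(A, comp$graph_index, reorder = TRUE)
  list(states = states, Zs = Zs, Ss = Ss, A = A, g = g)
}

internal_backward_stacked <- function(theta, comp, bucket_rows, act, T, sig_id,
                                      cache, dG) {
  d <- ncol(theta$embed)
  dA <- dG[comp$graph_index, , drop = FALSE]
  dSU <- row_softmax_bw(cache$A, dA)
  dstates <- rep(list(dSU), T + 1L)
  gW <- lapply(seq_len(T), function(t) vector("list", length(bucket_rows)))
  gM <- gW
  for (t in rev(seq_len(T))) {
    dZ <- apply_act_bw(cache$Zs[[t]], cache$states[[t + 1L]], dstates[[t + 1L]], act)
    Q <- matrix(0, comp$n_atoms, d)
    own <- matrix(0, comp$n_atoms, d)
    for (b in seq_along(bucket_rows)) {
      r <- bucket_rows[[b]]
      if (!length(r)) {
        gW[[t]][[b]] <- matrix(0, d, d)
        gM[[t]][[b]] <- matrix(0, d, d)
        next
      }
      dZr <- dZ[r, , drop = FALSE]
      gW[[t]][[b]] <- crossprod(dZr, cache$states[[t]][r, , drop = FALSE])
      gM[[t]][[b]] <- crossprod(dZr, cache$Ss[[t]][r, , drop = FALSE])
      own[r, ] <- dZr %*% theta$W[[t]][[b]]
      Q[r, ] <- dZr %*% theta$M[[t]][[b]]
    }
    dstates[[t]] <- dstates[[t]] + own + as.matrix(Matrix::t(comp$Aint) %*% Q)
  }
  gembed <- matrix(0, nrow(theta$embed), d)
  rs <- rowsum(dstates[[1L]], sig_id, reorder = FALSE)
  gembed[as.integer(rownames(rs)), ] <- rs
  list(embed = gembed, W = gW, M = gM)
}

# ---- external convolution (matrix form) ----

external_forward_mat <- function(theta, Aext, g, f_act, sigma_act, L) {
  Gs <- vector("list", L + 1L)
  Gs[[1L]] <- g
  Zs <- vector("list", L)
  AGs <- vector("list", L)
  for (l in seq_len(L)) {
    AG <- as.matrix(Aext %*% Gs[[l]])
    Z <- Gs[[l]] %*% t(theta$U[[l]]) + AG %*% t(theta$V[[l]])
    Gs[[l + 1L]] <- apply_act(Z, f_act)
    Zs[[l]] <- Z
    AGs[[l]] <- AG
  }
  SU <- Reduce(`+`, Gs)
  H <- apply_act(SU, sigma_act)
  list(Gs = Gs, Zs = Zs, AGs = AGs, SU = SU, H = H)
}

external_backward_mat <- function(theta, Aext, cache, dH, f_act, sigma_act, L) {
  dSU <- apply_act_bw(cache$SU, cache$H, dH, sigma_act)
  dGs <- rep(list(dSU), L + 1L)
  gU <- vector("list", L)
  gV <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dZ <- apply_act_bw(cache$Zs[[l]], cache$Gs[[l + 1L]], dGs[[l + 1L]], f_act)
    gU[[l]] <- crossprod(dZ, cache$Gs[[l]])
    gV[[l]] <- crossprod(dZ, cache$AGs[[l]])
    dGs[[l]] <- dGs[[l]] + dZ %*% theta$U[[l]] +
      as.matrix(Matrix::t(Aext) %*% (dZ %*% theta$V[[l]]))
  }
  list(U = gU, V = gV, dg = dGs[[1L]])
}

# ---- full model ----

# Build the trainable parameter tree and fixed metadata for a mode.
init_model <- function(gog, comp, config) {
  d <- config$d
  mode <- config$mode
  keys <- unique(comp$sig_keys)
  sig_id <- match(comp$sig_keys, keys)
  theta <- list()
  meta <- list(mode = mode, d = d, sig_keys = keys, sig_id = sig_id,
               T = config$T, L = config$L, degree_max = config$degree_max,
               activation_internal = config$activation_internal,
               activation_external = config$activation_external,
               sigma = config$sigma,
               bucket_rows = comp_buckets(comp, config$degree_max))
  h_dim <- d
  if (mode %in% c("dual", "internal_only")) {
    tab <- atom_table(keys, d, seed = config$seed, sd = config$embed_init_sd)
    theta$embed <- tab$entries
    icp <- internal_conv_params(d, config$T, config$degree_max,
                                config$activation_internal, seed = config$seed + 1L)
    theta$W <- icp$W
    theta$M <- icp$M
  }
  if (mode == "dual" && config$L > 0) {
    ecp <- external_conv_params(d, config$L, config$activation_external,
                                config$sigma, seed = config$seed + 2L)
    theta$U <- ecp$U
    theta$V <- ecp$V
  }
  if (mode == "embedding_only") {
    h_dim <- config$embedding_dim
    theta$free <- withr::with_seed(config$seed,
      rand_mat(comp$n_graphs, h_dim, config$embed_init_sd))
  }
  if (mode == "fingerprint") {
    h_dim <- config$fp_bits
  }
  meta$h_dim <- h_dim
  theta$P <- unclass(predictor_params(2L * h_dim, config$hidden_sizes,
                                      config$dropout, seed = config$seed + 3L,
                                      bias = config$predictor_bias))
  theta$P <- theta$P[c("W1", "b1", "W2", "b2", "W3", "b3")]
  theta$P <- theta$P[!vapply(theta$P, is.null, logical(1))]
  list(theta = theta, meta = meta)
}

predictor_view <- function(theta, meta, config) {
  structure(c(list(d_in = 2L * meta$h_dim, hidden = config$hidden_sizes,
                   dropout_rate = config$dropout), theta$P),
            class = "predictor_params")
}

# Forward to compound representations H (n x h_dim) with caches.
model_forward_h <- function(theta, meta, comp, Aext, fp = NULL) {
  mode <- meta$mode
  if (mode == "fingerprint") {
    return(list(H = fp))
  }
  if (mode == "embedding_only") {
    H <- row_softmax(theta$free)
    return(list(H = H))
  }
  ic <- internal_forward_stacked(theta, comp, meta$bucket_rows,
                                 meta$activation_internal, meta$T, meta$sig_id)
  if (mode == "internal_only" || meta$L == 0L) {
    H <- row_softmax(ic$g)
    return(list(H = H, ic = ic))
  }
  ec <- external_forward_mat(theta, Aext, ic$g, meta$activation_external,
                             meta$sigma, meta$L)
  list(H = ec$H, ic = ic, ec = ec)
}

model_backward_h <- function(theta, meta, comp, Aext, fwd, dH) {
  mode <- meta$mode
  grads <- list()
  if (mode == "fingerprint") return(grads)
  if (mode == "embedding_only") {
    grads$free <- row_softmax_bw(fwd$H, dH)
    return(grads)
  }
  if (mode == "internal_only" || meta$L == 0L) {
    dg <- row_softmax_bw(fwd$H, dH)
  } else {
    eb <- external_backward_mat(theta, Aext, fwd$ec, dH,
                                meta$activation_external, meta$sigma, meta$L)
    grads$U <- eb$U
    grads$V <- eb$V
    dg <- eb$dg
  }
  ib <- internal_backward_stacked(theta, comp, meta$bucket_rows,
                                  meta$activation_internal, meta$T,
                                  meta$sig_id, fwd$ic, dg)
  grads$embed <- ib$embed
  grads$W <- ib$W
  grads$M <- ib$M
  grads
}

# Loss and full gradient tree for one batch of labeled pairs.
model_loss_grad <- function(theta, meta, comp, Aext, config, pi, pj, labels,
                            train_mode = TRUE, fp = NULL, want_grad = TRUE) {
  fwd <- model_forward_h(theta, meta, comp, Aext, fp = fp)
  H <- fwd$H
  hd <- ncol(H)
  X <- cbind(H[pi, , drop = FALSE] + H[pj, , drop = FALSE],
             H[pi, , drop = FALSE] * H[pj, , drop = FALSE])
  pv <- predictor_view(theta, meta, config)
  pf <- predictor_forward(X, pv, train_mode = train_mode)
  ptrue <- pf$P[cbind(seq_along(labels), labels + 1L)]
  loss <- -sum(log(pmax(ptrue, 1e-12)))
  if (!want_grad) return(list(loss = loss, P = pf$P))
  dY <- pf$P
  dY[cbind(seq_along(labels), labels + 1L)] <-
    dY[cbind(seq_along(labels), labels + 1L)] - 1
  pb <- predictor_backward(pf, pv, dY)
  grads <- list()
  grads$P <- pb$grads[names(theta$P)]
  if (meta$mode != "fingerprint") {
    dS <- pb$dX[, seq_len(hd), drop = FALSE]
    dPr <- pb$dX[, hd + seq_len(hd), drop = FALSE]
    dHi <- dS + dPr * H[pj, , drop = FALSE]
    dHj <- dS + dPr * H[pi, , drop = FALSE]
    dH <- matrix(0, nrow(H), hd)
    agg <- rowsum(rbind(dHi, dHj), c(pi, pj), reorder = FALSE)
    dH[as.integer(rownames(agg)), ] <- agg
    grads <- c(model_backward_h(theta, meta, comp, Aext, fwd, dH), grads)
  }
  # align gradient tree with theta (fill missing with zeros, fix order)
  grads <- grads[names(theta)]
  names(grads) <- names(theta)
  list(loss = loss, grads = grads, P = pf$P)
}

# Eval-mode link probabilities for arbitrary pairs.
model_predict_pairs <- function(theta, meta, comp, Aext, config, pi, pj, fp = NULL) {
  out <- model_loss_grad(theta, meta, comp, Aext, config, pi, pj,
                         labels = integer(length(pi)), train_mode = FALSE,
                         fp = fp, want_grad = FALSE)
  out$P[, 2L]
}

# ---- parameter tree <-> flat vector ----

flatten_params <- function(theta) {
  unlist(theta, use.names = FALSE)
}

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  walk <- function(node) {
    if (is.list(node)) return(lapply(node, walk))
    n <- length(node)
    out <- flat[pos + seq_len(n)]
    pos <<- pos + n
    attributes(out) <- attributes(node)
    out
  }
  out <- walk(skeleton)
  stopifnot(pos == length(flat))
  out
}

# ---- Adam ----

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(flat_theta, flat_grad, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * flat_grad
  state$v <- beta2 * state$v + (1 - beta2) * flat_grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = flat_theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
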