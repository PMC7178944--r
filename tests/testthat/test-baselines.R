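test_that("CN and Jaccard match exhaustive set computation on a 6-node graph", {
  withr::with_seed(51, {
    # random 6-node graph
    all_pairs <- t(combn(6, 2))
    on <- runif(15) < 0.5
    edges <- all_pairs[on, , drop = FALSE]
  })
  adj <- lapply(1:6, function(k) {
    sort(c(edges[edges[, 1] == k, 2], edges[edges[, 2] == k, 1]))
  })
  pairs <- tibble::tibble(i = all_pairs[, 1], j = all_pairs[, 2])
  cn <- similarity_scores(adj, pairs, "common_neighbors")
  jc <- similarity_scores(adj, pairs, "jaccard")
  for (r in 1:15) {
    ni <- adj[[pairs$i[r]]]; nj <- adj[[pairs$j[r]]]
    expect_equal(cn[r], length(intersect(ni, nj)))
    expected_jc <- if (length(union(ni, nj)) == 0) 0 else
      length(intersect(ni, nj)) / length(union(ni, nj))
    expect_equal(jc[r], expected_jc)
  }
  expect_true(all(jc >= 0 & jc <= 1))
  expect_true(all(cn == round(cn)))
  # disjoint neighborhoods -> 0
  adj0 <- list(2L, 1L, 4L, 3L)
  p0 <- tibble::tibble(i = 1L, j = 3L)
  expect_equal(similarity_scores(adj0, p0, "common_neighbors"), 0)
  expect_equal(similarity_scores(adj0, p0, "jaccard"), 0)
})

test_that("Katz equals the truncated power series and is symmetric", {
  # K3, beta = 0.001, pair (1,2): sum_l beta^l (A^l)_12
  A <- matrix(1, 3, 3) - diag(3)
  adj <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  series <- 0
  P <- diag(3)
  for (l in 1:20) {
    P <- P %*% A
    series <- series + 0.001^l * P[1, 2]
  }
  got <- similarity_scores(adj, tibble::tibble(i = 1L, j = 2L), "katz", beta = 0.001)
  expect_equal(got, series, tolerance = 1e-10)
  expect_equal(got, 1.001e-3, tolerance = 1e-5)

  # random 8-node graph: direct solve vs truncated series, both orientations
  withr::with_seed(53, {
    ap <- t(combn(8, 2))
    on <- runif(nrow(ap)) < 0.4
    e <- ap[on, , drop = FALSE]
  })
  A8 <- matrix(0, 8, 8)
  A8[e] <- 1
  A8 <- A8 + t(A8)
  adj8 <- lapply(1:8, function(k) which(A8[k, ] == 1))
  beta <- 0.05
  S <- matrix(0, 8, 8); P <- diag(8)
  for (l in 1:200) { P <- P %*% A8; S <- S + beta^l * P }
  pr <- tibble::tibble(i = ap[, 1], j = ap[, 2])
  kz <- similarity_scores(adj8, pr, "katz", beta = beta)
  expect_equal(kz, S[cbind(pr$i, pr$j)], tolerance = 1e-10)
  kz_rev <- similarity_scores(adj8, tibble::tibble(i = pr$j, j = pr$i), "katz", beta = beta)
  expect_equal(kz, kz_rev, tolerance = 1e-12)
  expect_true(all(kz >= 0))
})

test_that("Katz rejects beta at or above the divergence threshold", {
  adj <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))   # K3, spectral radius 2
  expect_error(similarity_scores(adj, tibble::tibble(i = 1L, j = 2L), "katz", beta = 0.6),
               class = "gognn_katz_beta_error")
})

test_that("hashed fingerprints are deterministic, label-sensitive, and invariant", {
  # single heavy atom, radius 0 -> exactly one bit
  methane <- carbon_atom()
  fp0 <- morgan_fingerprint(methane, radius = 0)
  expect_equal(sum(fp0$bits), 1)
  # different heteroatom -> different bits
  ammonia <- internal_graph("n", atom_signature("N", 3, 3, 0))
  expect_false(identical(which(morgan_fingerprint(ammonia, 0)$bits == 1),
                         which(fp0$bits == 1)))
  # isomorphic relabeling -> identical fingerprint
  g <- star4_graph()
  perm <- c(4L, 2L, 1L, 3L)
  inv <- order(perm)
  g2 <- internal_graph("perm", g$atoms[inv, c("element", "valence", "hydrogen_count", "aromatic")],
                       cbind(perm[gognn:::internal_edge_matrix(g)[, 1]],
                             perm[gognn:::internal_edge_matrix(g)[, 2]]))
  expect_identical(morgan_fingerprint(g, 2)$bits, morgan_fingerprint(g2, 2)$bits)
  # stable across calls
  expect_identical(morgan_fingerprint(g, 2)$bits, morgan_fingerprint(g, 2)$bits)
})

test_that("fingerprint mode freezes features and keeps predictor symmetry", {
  gg <- toy_gog(8, density = 0.4, seed = 57)$gog
  fp <- fingerprint_matrix(gg, radius = 2, nbits = 64)
  expect_equal(dim(fp), c(8, 64))
  expect_true(all(fp %in% c(0, 1)))
  # identical compounds: product block = h^2, sum block = 2h
  h <- fp[1, ]
  expect_equal(pair_features(h, h), c(2 * h, h^2))
  # gradient tree in fingerprint mode contains only predictor arrays
  cfg <- gognn_config(mode = "fingerprint", fp_bits = 64, hidden_sizes = c(6, 4),
                      dropout = 0, seed = 1)
  comp <- gognn:::compile_gog(gg)
  model <- gognn:::init_model(gg, comp, cfg)
  Aext <- gognn:::edge_matrix_to_sparse(matrix(integer(0), ncol = 2), 8)
  lg <- gognn:::model_loss_grad(model$theta, model$meta, comp, Aext, cfg,
                                c(1L, 2L), c(3L, 4L), c(1L, 0L),
                                train_mode = FALSE, fp = fp)
  expect_named(lg$grads, "P")
})
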