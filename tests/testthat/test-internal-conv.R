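test_that("internal_step handles degenerate and identity-weight cases", {
  g1 <- carbon_atom()
  p <- internal_conv_params(d = 2, T = 1, seed = 1)
  # zero W on the degree-0 bucket -> ReLU(0) = 0
  p$W[[1]][[1]] <- matrix(0, 2, 2)
  out <- internal_step(matrix(c(1, -2), 1, 2), g1, p, 1)
  expect_equal(as.numeric(out), c(0, 0))

  # 2-atom edge with identity W = M and identity activation:
  # each output = own state + neighbor state
  g2 <- internal_graph("e2", rbind(atom_signature("C", 4, 3, 1),
                                   atom_signature("C", 4, 3, 1)),
                       cbind(1, 2))
  p2 <- internal_conv_params(d = 2, T = 1, activation = "identity", seed = 1)
  for (b in seq_along(p2$W[[1]])) {
    p2$W[[1]][[b]] <- diag(2)
    p2$M[[1]][[b]] <- diag(2)
  }
  st <- rbind(c(1, 2), c(10, 20))
  expect_equal(internal_step(st, g2, p2, 1), rbind(c(11, 22), c(11, 22)))

  expect_error(internal_step(matrix(0, 3, 2), g2, p2, 1), class = "gognn_dim_error")
})

test_that("internal_step and internal_convolve match the straight-line oracle", {
  withr::with_seed(7, {
    g <- path3_graph()
    p <- internal_conv_params(d = 2, T = 2, seed = 7)
    tab <- atom_table(list(g), d = 2, seed = 7)
    v0 <- tab$entries[match(gognn:::signature_key(g$atoms), tab$keys), ]
    oracle <- oracle_internal_states(g, v0, p)
    v <- v0
    for (t in 1:2) {
      v <- internal_step(v, g, p, t)
      expect_equal(v, oracle[[t + 1]], tolerance = 1e-6)
    }
    expect_equal(internal_convolve(g, tab, p), oracle_internal_g(g, v0, p),
                 tolerance = 1e-6)
  })
  # 4-atom star, T = 2
  withr::with_seed(11, {
    g <- star4_graph()
    p <- internal_conv_params(d = 3, T = 2, seed = 11)
    tab <- atom_table(list(g), d = 3, seed = 11)
    v0 <- tab$entries[match(gognn:::signature_key(g$atoms), tab$keys), ]
    expect_equal(internal_convolve(g, tab, p), oracle_internal_g(g, v0, p),
                 tolerance = 1e-6)
  })
})

test_that("per-atom softmax pooling makes components of g sum to atom count", {
  g1 <- carbon_atom()
  p <- internal_conv_params(d = 4, T = 1, seed = 3)
  tab <- atom_table(list(g1), d = 4, seed = 3)
  expect_equal(sum(internal_convolve(g1, tab, p)), 1, tolerance = 1e-10)
  g <- star4_graph()
  tab2 <- atom_table(list(g), d = 4, seed = 3)
  expect_equal(sum(internal_convolve(g, tab2, p)), 4, tolerance = 1e-10)
})

test_that("internal convolution is invariant to atom relabeling", {
  g <- star4_graph()
  # permuted copy: relabel atoms with adjacency permuted consistently
  perm <- c(3L, 1L, 4L, 2L)   # new position of old atom k
  inv <- order(perm)
  atoms2 <- g$atoms[inv, c("element", "valence", "hydrogen_count", "aromatic")]
  bonds <- gognn:::internal_edge_matrix(g)
  bonds2 <- cbind(perm[bonds[, 1]], perm[bonds[, 2]])
  g2 <- internal_graph("perm", atoms2, bonds2)
  p <- internal_conv_params(d = 3, T = 2, seed = 5)
  tab <- atom_table(list(g), d = 3, seed = 5)
  expect_equal(internal_convolve(g, tab, p), internal_convolve(g2, tab, p),
               tolerance = 1e-6)
})

test_that("isomorphic graphs with identical signatures give identical g", {
  a <- toy_gog(2, seed = 31)$gog$compounds[[1]]
  b <- internal_graph("copy", a$atoms[, c("element", "valence", "hydrogen_count", "aromatic")],
                      gognn:::internal_edge_matrix(a))
  p <- internal_conv_params(d = 4, T = 1, seed = 2)
  tab <- atom_table(list(a), d = 4, seed = 2)
  expect_identical(internal_convolve(a, tab, p), internal_convolve(b, tab, p))
})

test_that("unseen signatures fall back with a warning", {
  g <- carbon_atom()
  tab <- atom_table("N:3:2:1:0", d = 2, seed = 1)
  p <- internal_conv_params(d = 2, T = 1, seed = 1)
  expect_warning(v <- internal_convolve(g, tab, p), "fallback")
  expect_length(v, 2)
})

test_that("stacked engine forward equals the per-graph reference path", {
  gg <- toy_gog(8, density = 0.3, seed = 13)$gog
  cfg <- gognn_config(mode = "dual", d = 5, T = 2, L = 0, dropout = 0, seed = 17)
  comp <- gognn:::compile_gog(gg)
  model <- gognn:::init_model(gg, comp, cfg)
  ic <- gognn:::internal_forward_stacked(model$theta, comp, model$meta$bucket_rows,
                                         "relu", 2L, model$meta$sig_id)
  p <- internal_conv_params(d = 5, T = 2, seed = 999)
  p$W <- model$theta$W
  p$M <- model$theta$M
  tab <- structure(list(d = 5, keys = model$meta$sig_keys,
                        entries = model$theta$embed, seed = cfg$seed),
                   class = "atom_table")
  for (k in c(1, 4, 8)) {
    expect_equal(as.numeric(ic$g[k, ]),
                 internal_convolve(gg$compounds[[k]], tab, p), tolerance = 1e-10)
  }
})
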