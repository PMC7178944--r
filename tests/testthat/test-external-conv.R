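test_that("external_convolve degenerate cases", {
  # L = 0: h_i = softmax(g_i), rows sum to 1
  p0 <- external_conv_params(d = 3, L = 0, seed = 1)
  g <- matrix(rnorm(12), 4, 3)
  h <- external_convolve(g, p0, rep(list(integer(0)), 4))
  expect_equal(rowSums(h), rep(1, 4), tolerance = 1e-10)
  expect_equal(h, gognn:::row_softmax(g), tolerance = 1e-12)

  # isolated node with U = 0: its step output is softmax(0) = uniform
  p1 <- external_conv_params(d = 3, L = 1, seed = 2)
  p1$U[[1]] <- matrix(0, 3, 3)
  withr::with_seed(4, g1 <- matrix(rnorm(3), 1, 3))
  cache <- gognn:::external_forward_mat(list(U = p1$U, V = p1$V),
                                        gognn:::edge_matrix_to_sparse(matrix(integer(0), ncol = 2), 1),
                                        g1, "softmax", "softmax", 1L)
  expect_equal(as.numeric(cache$Gs[[2]]), rep(1 / 3, 3), tolerance = 1e-12)

  expect_error(external_convolve(g, p0, rep(list(integer(0)), 3)),
               class = "gognn_dim_error")
  expect_error(external_convolve(g, p0, rep(list(9L), 4)),
               class = "gognn_dim_error")
})

test_that("external_convolve matches the straight-line oracle on a 4-cycle", {
  withr::with_seed(13, {
    adj <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))
    g <- matrix(rnorm(12), 4, 3)
    p <- external_conv_params(d = 3, L = 2, seed = 13)
    expect_equal(external_convolve(g, p, adj), oracle_external_h(adj, g, p),
                 tolerance = 1e-6)
  })
})

test_that("external convolution is permutation-equivariant and row-normalized", {
  withr::with_seed(19, {
    gg <- toy_gog(7, density = 0.4, seed = 19)$gog
    adj <- gg$external_adjacency
    g <- matrix(rnorm(7 * 4), 7, 4)
    p <- external_conv_params(d = 4, L = 2, seed = 19)
    h <- external_convolve(g, p, adj)
    expect_equal(rowSums(h), rep(1, 7), tolerance = 1e-10)
    # permute compounds
    perm <- sample(7)
    inv <- order(perm)
    adj_p <- lapply(inv, function(old) sort(perm[adj[[old]]]))
    h_p <- external_convolve(g[inv, ], p, adj_p)
    expect_equal(h_p, h[inv, ], tolerance = 1e-10)
  })
})

test_that("L-step convolution only sees compounds within external distance L", {
  # path graph 1-2-3-4-5; perturbing node 5's input cannot change node 1's
  # output when L = 2
  adj <- list(2L, c(1L, 3L), c(2L, 4L), c(3L, 5L), 4L)
  withr::with_seed(23, {
    g <- matrix(rnorm(5 * 3), 5, 3)
    p <- external_conv_params(d = 3, L = 2, seed = 23)
  })
  h1 <- external_convolve(g, p, adj)
  g2 <- g
  g2[5, ] <- g2[5, ] + 10
  h2 <- external_convolve(g2, p, adj)
  expect_equal(h2[1, ], h1[1, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(h2[3, ], h1[3, ], tolerance = 1e-8)))
})

test_that("matrix-form engine equals the reference external path", {
  gg <- toy_gog(9, density = 0.3, seed = 29)$gog
  withr::with_seed(29, g <- matrix(rnorm(9 * 4), 9, 4))
  p <- external_conv_params(d = 4, L = 3, seed = 29)
  Aext <- gognn:::edge_matrix_to_sparse(gognn:::external_edge_matrix(gg), 9)
  ec <- gognn:::external_forward_mat(list(U = p$U, V = p$V), Aext, g,
                                     "softmax", "softmax", 3L)
  expect_equal(ec$H, external_convolve(g, p, gg$external_adjacency),
               tolerance = 1e-12)
})
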