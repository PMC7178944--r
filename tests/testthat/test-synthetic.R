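test_that("motif planting is exhaustive and exclusive", {
  spec <- synthetic_spec(size_range = c(3L, 3L), motif_fraction = 1, seed = 81)
  withr::with_seed(81, {
    for (r in 1:20) {
      g <- gen_internal_graph(spec, id = paste0("m", r), motif = TRUE)
      expect_true(gognn:::has_motif(g))
    }
  })
  # non-motif compounds never contain the sulfur triangle
  spec2 <- synthetic_spec(size_range = c(6L, 12L), seed = 82)
  withr::with_seed(82, {
    for (r in 1:30) {
      g <- gen_internal_graph(spec2, id = paste0("n", r), motif = FALSE)
      expect_false(gognn:::has_motif(g))
    }
  })
})

test_that("generated molecules are connected, valence-capped and consistent", {
  spec <- synthetic_spec(size_range = c(8L, 20L), motif_fraction = 0.5, seed = 83)
  withr::with_seed(83, {
    for (r in 1:15) {
      g <- gen_internal_graph(spec, id = "x", motif = r %% 2 == 0)
      expect_true(all(g$atoms$degree <= 4))
      expect_equal(g$atoms$degree, lengths(g$adjacency))
      # connectivity: breadth-first search reaches every atom
      seen <- logical(nrow(g$atoms)); seen[1] <- TRUE
      queue <- 1L
      while (length(queue)) {
        k <- queue[1]; queue <- queue[-1]
        for (m in g$adjacency[[k]]) if (!seen[m]) { seen[m] <- TRUE; queue <- c(queue, m) }
      }
      expect_true(all(seen))
    }
  })
  # seeded reproducibility
  g1 <- withr::with_seed(9, gen_internal_graph(spec, "a", motif = TRUE))
  g2 <- withr::with_seed(9, gen_internal_graph(spec, "a", motif = TRUE))
  expect_identical(g1, g2)
})

test_that("gen_gog hits the target density within binomial error", {
  spec <- synthetic_spec(n_compounds = 500, target_density = 0.05,
                         p_in = 1, p_out = 1, motif_boost = 1, seed = 85)
  gg <- gen_gog(spec)
  st <- gog_stats(gg$gog)
  n_pairs <- st$n_pairs
  sd3 <- 3 * sqrt(0.05 * 0.95 / n_pairs)
  expect_lt(abs(st$density - 0.05), sd3)
  expect_identical(gen_gog(spec)$gog$external_adjacency, gg$gog$external_adjacency)
})

test_that("power-law mode produces a heavier degree tail than larger gamma", {
  hill <- function(deg) {
    d <- sort(deg[deg > 0], decreasing = TRUE)
    k <- max(5, ceiling(0.1 * length(d)))
    xs <- d[1:k]
    1 + k / sum(log(xs / xs[k]))
  }
  g_heavy <- gen_gog(synthetic_spec(n_compounds = 400, target_density = 0.05,
                                    degree_model = "powerlaw", powerlaw_gamma = 2.1,
                                    seed = 87))
  g_light <- gen_gog(synthetic_spec(n_compounds = 400, target_density = 0.05,
                                    degree_model = "powerlaw", powerlaw_gamma = 3.5,
                                    seed = 87))
  a_heavy <- hill(lengths(g_heavy$gog$external_adjacency))
  a_light <- hill(lengths(g_light$gog$external_adjacency))
  expect_lt(a_heavy, a_light)
})

test_that("motif boost raises the link rate among motif-motif pairs", {
  spec <- synthetic_spec(n_compounds = 300, target_density = 0.05,
                         motif_boost = 5, motif_fraction = 0.5,
                         p_in = 1, p_out = 1, seed = 89)
  gg <- gen_gog(spec)
  tr <- gg$truth
  e <- gognn:::external_edge_matrix(gg$gog)
  n <- 300
  keys <- gognn:::pair_key(e[, 1], e[, 2], n)
  i <- rep.int(seq_len(n - 1), (n - 1):1)
  j <- sequence((n - 1):1, from = 2:n)
  both <- tr$motif[i] & tr$motif[j]
  linked <- gognn:::pair_key(i, j, n) %in% keys
  rate_mm <- mean(linked[both])
  rate_other <- mean(linked[!both])
  expect_gt(rate_mm, 2 * rate_other)
  pt <- prop.test(x = c(sum(linked[both]), sum(linked[!both])),
                  n = c(sum(both), sum(!both)), alternative = "greater")
  expect_lt(pt$p.value, 1e-6)
})

test_that("generated GoGs pass full validation on rebuild", {
  gg <- toy_gog(30, density = 0.2, seed = 91)$gog
  e <- gognn:::external_edge_matrix(gg)
  expect_silent(rebuilt <- build_gog(gg$compounds, cbind(gg$ids[e[, 1]],
                                                         gg$ids[e[, 2]])))
  expect_equal(rebuilt$external_adjacency, gg$external_adjacency)
})
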