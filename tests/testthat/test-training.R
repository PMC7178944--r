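memorization_fixture <- function() {
  gg <- toy_gog(10, density = 0.3, seed = 21)$gog
  sp <- make_split(gg, n_train_pos = 4, n_train_neg = 4,
                   test_spec = list(n_test = 10), seed = 2)
  list(gog = gg, split = sp)
}

test_that("training is deterministic under a fixed seed", {
  fx <- memorization_fixture()
  cfg <- gognn_config(mode = "dual", d = 8, T = 1, L = 1, batch_size = 8,
                      epochs = 5, validation_fraction = 0, seed = 33)
  f1 <- train_gognn(fx$gog, fx$split, cfg)
  f2 <- train_gognn(fx$gog, fx$split, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$theta, f2$theta)
})

test_that("epoch-one loss on a balanced batch sits near chance level", {
  # with near-zero random logits the expected per-pair loss is ln 2
  fx <- memorization_fixture()
  cfg <- gognn_config(mode = "dual", d = 8, T = 1, L = 1, batch_size = 8,
                      epochs = 1, dropout = 0, validation_fraction = 0, seed = 35)
  fit <- train_gognn(fx$gog, fx$split, cfg)
  n <- nrow(fx$split$train)
  expect_lt(abs(fit$history$loss[1] - n * log(2)) / (n * log(2)), 0.2)
})

test_that("the dual model memorizes a tiny fixture and the loss collapses", {
  fx <- memorization_fixture()
  cfg <- gognn_config(mode = "dual", d = 16, T = 1, L = 1, batch_size = 8,
                      epochs = 200, learning_rate = 0.001, dropout = 0.2,
                      validation_fraction = 0, seed = 9)
  fit <- train_gognn(fx$gog, fx$split, cfg)
  final <- fit$history$loss[nrow(fit$history)]
  expect_lt(final, 0.05)
  # eventually decreasing: final at least 10x below the initial loss
  expect_lt(final, fit$history$loss[1] / 10)
})

test_that("ablation modes take the documented forward shortcuts", {
  fx <- memorization_fixture()
  comp <- gognn:::compile_gog(fx$gog)
  Aext <- gognn:::edge_matrix_to_sparse(fx$split$message_edges, 10)
  # internal_only: h = softmax(g), external weights absent
  cfg_i <- gognn_config(mode = "internal_only", d = 6, T = 1, dropout = 0, seed = 3)
  m_i <- gognn:::init_model(fx$gog, comp, cfg_i)
  expect_false(any(c("U", "V") %in% names(m_i$theta)))
  fwd <- gognn:::model_forward_h(m_i$theta, m_i$meta, comp, Aext)
  expect_equal(fwd$H, gognn:::row_softmax(fwd$ic$g), tolerance = 1e-12)
  # embedding_only: h = softmax(free 64-d vectors), no convolution weights
  cfg_e <- gognn_config(mode = "embedding_only", dropout = 0, seed = 3)
  m_e <- gognn:::init_model(fx$gog, comp, cfg_e)
  expect_named(m_e$theta, c("free", "P"))
  expect_equal(ncol(m_e$theta$free), 64)
  fwd_e <- gognn:::model_forward_h(m_e$theta, m_e$meta, comp, Aext)
  expect_equal(fwd_e$H, gognn:::row_softmax(m_e$theta$free), tolerance = 1e-12)
})

test_that("test labels cannot influence training", {
  fx <- memorization_fixture()
  cfg <- gognn_config(mode = "dual", d = 6, T = 1, L = 1, batch_size = 8,
                      epochs = 3, validation_fraction = 0, seed = 13)
  f1 <- train_gognn(fx$gog, fx$split, cfg)
  sp2 <- fx$split
  sp2$test$label <- rev(sp2$test$label)
  f2 <- train_gognn(fx$gog, sp2, cfg)
  expect_identical(rlang::hash(f1$theta), rlang::hash(f2$theta))
})

test_that("training aborts with a divergence report on non-finite loss", {
  fx <- memorization_fixture()
  cfg <- gognn_config(mode = "dual", d = 6, T = 1, L = 1, batch_size = 8,
                      epochs = 2, learning_rate = Inf, validation_fraction = 0,
                      seed = 15)
  expect_error(train_gognn(fx$gog, fx$split, cfg),
               class = "gognn_divergence_error")
})

test_that("tidy, glance and autoplot expose the fit", {
  fx <- memorization_fixture()
  cfg <- gognn_config(mode = "dual", d = 6, T = 1, L = 1, batch_size = 8,
                      epochs = 3, validation_fraction = 0.2, seed = 17)
  fit <- train_gognn(fx$gog, fx$split, cfg)
  td <- tidy(fit)
  expect_named(td, c("epoch", "loss", "val_roc_auc"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(gl$mode, "dual")
  expect_gt(gl$n_parameters, 0)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_roc(runif(20), rbinom(20, 1, 0.5)), "ggplot")
})
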