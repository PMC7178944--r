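# Benchmark runners shared by the acceptance suite: fixed study conditions,
# seeded end to end.

dense_benchmark_seed <- function(s) {
  spec <- synthetic_spec(n_compounds = 300, target_density = 0.09,
                         degree_model = "powerlaw", powerlaw_gamma = 2.2,
                         motif_boost = 5, p_in = 4, p_out = 1,
                         motif_fraction = 0.5, n_communities = 3, seed = s)
  gg <- gen_gog(spec)
  sp <- make_split(gg$gog, n_train_pos = 1000, n_train_neg = 1000,
                   test_spec = list(n_test = 3000), seed = s + 1)
  out <- c()
  for (mode in c("dual", "internal_only")) {
    cfg <- gognn_config(mode = mode, d = 32, T = 1, L = 1, batch_size = 128,
                        epochs = 30, learning_rate = 0.001, dropout = 0.2,
                        validation_fraction = 0.1, seed = s + 2)
    fit <- train_gognn(gg$gog, sp, cfg)
    pr <- predict(fit, gg$gog, sp$test)
    out[mode] <- roc_auc(pr$score, sp$test$label)
  }
  kz <- baseline_scores(gg$gog, sp$message_edges, sp$test, index = "katz")
  out["katz"] <- roc_auc(kz$score, sp$test$label)
  out
}

sparse_benchmark_seed <- function(s) {
  spec <- synthetic_spec(n_compounds = 600, target_density = 0.0003,
                         degree_model = "bernoulli",
                         motif_boost = 5, p_in = 4, p_out = 1,
                         motif_fraction = 0.5, n_communities = 3, seed = s)
  gg <- gen_gog(spec)
  m <- gog_stats(gg$gog)$n_edges
  ntp <- min(24, m - 32)
  sp <- make_split(gg$gog, n_train_pos = 30, n_train_neg = 30,
                   test_spec = list(n_test_pos = ntp, n_test_neg = 2000),
                   seed = s + 1)
  out <- c()
  kz <- baseline_scores(gg$gog, sp$message_edges, sp$test, index = "katz")
  out["katz"] <- roc_auc(kz$score, sp$test$label)
  for (mode in c("embedding_only", "fingerprint")) {
    # sixty training pairs: a hotter, longer schedule, no dropout noise,
    # best-epoch selection on the held-out development fraction
    cfg <- gognn_config(mode = mode, batch_size = 64, epochs = 300,
                        learning_rate = 0.01, dropout = 0,
                        validation_fraction = 0.15, seed = s + 2)
    fit <- train_gognn(gg$gog, sp, cfg)
    pr <- predict(fit, gg$gog, sp$test)
    out[mode] <- roc_auc(pr$score, sp$test$label)
  }
  out
}

null_benchmark <- function(seed = 301) {
  spec <- synthetic_spec(n_compounds = 200, target_density = 0.05,
                         motif_boost = 1, p_in = 1, p_out = 1,
                         motif_fraction = 0.5, seed = seed)
  gg <- gen_gog(spec)
  sp <- make_split(gg$gog, n_train_pos = 300, n_train_neg = 300,
                   test_spec = list(n_test_pos = 120, n_test_neg = 1200),
                   seed = seed + 1)
  out <- c()
  for (mode in c("dual", "internal_only", "embedding_only", "fingerprint")) {
    cfg <- gognn_config(mode = mode, d = 16, T = 1, L = 1, batch_size = 128,
                        epochs = 15, validation_fraction = 0, seed = seed + 2)
    fit <- train_gognn(gg$gog, sp, cfg)
    pr <- predict(fit, gg$gog, sp$test)
    out[mode] <- roc_auc(pr$score, sp$test$label)
  }
  for (ix in c("cn", "jaccard", "katz")) {
    sc <- baseline_scores(gg$gog, sp$message_edges, sp$test, index = ix)
    out[ix] <- roc_auc(sc$score, sp$test$label)
  }
  list(auc = out, se = sqrt((120 + 1200 + 1) / (12 * 120 * 1200)))
}
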