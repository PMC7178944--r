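# Negative sampling and train/test splits.

all_edge_keys <- function(gog) {
  e <- external_edge_matrix(gog)
  n <- length(gog$compounds)
  if (NROW(e) == 0) numeric(0) else pair_key(e[, 1], e[, 2], n)
}

pairs_tibble <- function(i, j, label, gog) {
  tibble::tibble(
    i = as.integer(i), j = as.integer(j),
    id_i = gog$ids[i], id_j = gog$ids[j],
    label = as.integer(label)
  )
}

#' Sample negative (no-link) compound pairs
#'
#' Draws n distinct unordered compound pairs uniformly without replacement
#' from the pairs that are not edges of the external network and not in the
#' exclusion set. Observed networks carry only positive links, so sampled
#' no-links stand in for negatives.
#'
#' @param gog A `gog`.
#' @param n Number of pairs to draw.
#' @param exclude Optional 2-column matrix of compound index pairs to avoid.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A tibble with columns i, j, id_i, id_j, label (all 0).
#' @export
sample_negatives <- function(gog, n, exclude = NULL, seed = 1L) {
  nc <- length(gog$compounds)
  n_pairs <- nc * (nc - 1) / 2
  forbidden <- all_edge_keys(gog)
  if (!is.null(exclude) && NROW(exclude) > 0) {
    forbidden <- c(forbidden, pair_key(exclude[, 1], exclude[, 2], nc))
  }
  forbidden <- unique(forbidden)
  if (n_pairs - length(forbidden) < n) {
    abort("not enough non-edges to sample the requested negatives",
          class = "gognn_insufficient_non_edges_error")
  }
  keys <- withr::with_seed(seed, {
    got <- numeric(0)
    # rejection sampling; falls back to enumeration for near-saturated graphs
    for (round in 1:40) {
      need <- n - length(got)
      if (need <= 0) break
      r <- sample.int(n_pairs, min(n_pairs, need * 2 + 16))
      ij <- pair_rank_to_ij(r, nc)
      k <- pair_key(ij[, 1], ij[, 2], nc)
      k <- setdiff(unique(k), c(forbidden, got))
      got <- c(got, head(k, need))
    }
    if (length(got) < n) {
      allr <- seq_len(n_pairs)
      ij <- pair_rank_to_ij(allr, nc)
      k <- pair_key(ij[, 1], ij[, 2], nc)
      pool <- setdiff(k, c(forbidden, got))
      got <- c(got, sample(pool, n - length(got)))
    }
    got
  })
  ij <- key_to_pair(keys, nc)
  pairs_tibble(ij[, 1], ij[, 2], 0L, gog)
}

#' Train/test split with negative sampling
#'
#' Samples training positives from the observed links and training negatives
#' from the no-links; the test set is disjoint from training. By default the
#' test set preserves the network's label imbalance: test pairs are drawn
#' uniformly from pairs outside the training set and labeled by edge
#' membership, so the positive fraction matches the link density up to
#' binomial noise. Explicit test counts may be given instead. Message-passing
#' edges are the training positives only, so representations never see test
#' links.
#'
#' @param gog A `gog`.
#' @param n_train_pos,n_train_neg Training pair counts.
#' @param test_spec Either `list(n_test = k)` for an imbalance-preserving draw
#'   of k pairs, or `list(n_test_pos = a, n_test_neg = b)` for explicit
#'   counts, or NULL (the default) for an imbalance-preserving draw of up to
#'   2000 pairs capped at what the network can supply.
#' @param seed Integer seed.
#' @return An object of class `gognn_split`: tibbles `train` and `test`
#'   (columns i, j, id_i, id_j, label) plus `message_edges`, the train-positive
#'   index pairs.
#' @export
make_split <- function(gog, n_train_pos, n_train_neg,
                       test_spec = NULL, seed = 1L) {
  nc <- length(gog$compounds)
  n_pairs <- nc * (nc - 1) / 2
  if (is.null(test_spec)) {
    test_spec <- list(n_test = min(2000, n_pairs - n_train_pos - n_train_neg))
  }
  edges <- external_edge_matrix(gog)
  if (NROW(edges) < n_train_pos) {
    abort("fewer observed links than requested training positives",
          class = "gognn_infeasible_split_error")
  }
  edge_keys <- pair_key(edges[, 1], edges[, 2], nc)
  withr::with_seed(seed, {
    pos_idx <- sample.int(NROW(edges), n_train_pos)
    train_pos <- edges[pos_idx, , drop = FALSE]
    neg_seed <- sample.int(.Machine$integer.max, 1)
    test_seed <- sample.int(.Machine$integer.max, 1)
  })
  train_neg <- sample_negatives(gog, n_train_neg, seed = neg_seed)
  train <- rbind(
    pairs_tibble(train_pos[, 1], train_pos[, 2], 1L, gog),
    train_neg
  )
  train_keys <- pair_key(train$i, train$j, nc)
  test <- withr::with_seed(test_seed, {
    if (!is.null(test_spec$n_test)) {
      need <- test_spec$n_test
      got <- numeric(0)
      for (round in 1:40) {
        if (length(got) >= need) break
        r <- sample.int(n_pairs, min(n_pairs, (need - length(got)) * 2 + 16))
        ij <- pair_rank_to_ij(r, nc)
        k <- pair_key(ij[, 1], ij[, 2], nc)
        k <- setdiff(unique(k), c(train_keys, got))
        got <- c(got, head(k, need - length(got)))
      }
      if (length(got) < need) {
        abort("cannot draw the requested test pairs", class = "gognn_infeasible_split_error")
      }
      ij <- key_to_pair(got, nc)
      lab <- as.integer(got %in% edge_keys)
      pairs_tibble(ij[, 1], ij[, 2], lab, gog)
    } else {
      rest_keys <- setdiff(edge_keys, train_keys)
      if (length(rest_keys) < test_spec$n_test_pos) {
        abort("not enough held-out links for the requested test positives",
              class = "gognn_infeasible_split_error")
      }
      pk <- sample(rest_keys, test_spec$n_test_pos)
      ijp <- key_to_pair(pk, nc)
      tn_seed <- sample.int(.Machine$integer.max, 1)
      tneg <- sample_negatives(gog, test_spec$n_test_neg,
                               exclude = cbind(train$i, train$j), seed = tn_seed)
      rbind(pairs_tibble(ijp[, 1], ijp[, 2], 1L, gog), tneg)
    }
  })
  structure(list(train = train, test = test,
                 message_edges = unname(train_pos)),
            class = "gognn_split")
}

#' @export
print.gognn_split <- function(x, ...) {
  cat(sprintf("<gognn_split: %d train (%d+/%d-), %d test (%d+/%d-)>\n",
              nrow(x$train), sum(x$train$label == 1), sum(x$train$label == 0),
              nrow(x$test), sum(x$test$label == 1), sum(x$test$label == 0)))
  invisible(x)
}
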