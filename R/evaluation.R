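# Imbalance-aware evaluation: ROC-AUC and PR-AUC.

#' ROC-AUC (rank / Mann-Whitney form)
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted half: computed from midranks, so it is exact under arbitrary
#' ties and invariant to strictly monotone score transforms.
#'
#' @param scores Numeric score vector (higher = more link-like).
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    abort("ROC-AUC requires both classes", class = "gognn_single_class_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' PR-AUC (average precision)
#'
#' Area under the precision-recall curve by the average-precision convention:
#' sum over distinct score thresholds of (recall increment) x (precision at
#' threshold), with no linear interpolation. Tied scores enter as one
#' threshold block.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; positives must be present.
#' @return Average precision in (0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1)
  if (np == 0) abort("PR-AUC requires positives", class = "gognn_single_class_error")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # threshold blocks over distinct scores
  last_of_block <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[last_of_block]
  n_pred <- last_of_block
  precision <- tp / n_pred
  recall <- tp / np
  sum(diff(c(0, recall)) * precision)
}

#' Metrics report for a prediction set
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return One-row tibble: roc_auc, pr_auc, n_pos, n_neg, positive_fraction.
#' @export
metrics_report <- function(scores, labels) {
  labels <- as.integer(labels)
  tibble::tibble(
    roc_auc = roc_auc(scores, labels),
    pr_auc = pr_auc(scores, labels),
    n_pos = sum(labels == 1),
    n_neg = sum(labels == 0),
    positive_fraction = mean(labels == 1)
  )
}
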