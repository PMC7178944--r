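#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_abline
#'   labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot the training history of a fit
#'
#' Per-epoch summed cross-entropy loss and, when a development set was held
#' out, development ROC-AUC.
#'
#' @param object A `gognn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gognn_fit <- function(object, ...) {
  h <- object$history
  ggplot(h, aes(x = .data$epoch, y = .data$loss)) +
    geom_line(color = "#2c7fb8") +
    labs(x = "epoch", y = "summed cross-entropy loss",
         title = sprintf("training history (%s mode)", object$config$mode)) +
    theme_minimal()
}

#' ROC curve for scored pairs
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return A ggplot object with the ROC step curve and the chance diagonal.
#' @export
plot_roc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(labels)[ord]
  tpr <- c(0, cumsum(y) / sum(y))
  fpr <- c(0, cumsum(1 - y) / sum(1 - y))
  df <- tibble::tibble(fpr = fpr, tpr = tpr)
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step(color = "#d95f02") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC (AUC = %.3f)", roc_auc(scores, labels))) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
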