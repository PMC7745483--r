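#' Ranking and threshold classification metrics
#'
#' Computes the seven evaluation metrics: AUPR (area under the
#' precision-recall curve by the step-wise average-precision convention —
#' no trapezoidal interpolation, which is optimistic under heavy class
#' imbalance), AUC (rank statistic with tie correction), and the
#' confusion-matrix metrics F1, accuracy, recall, specificity and precision
#' at a fixed score threshold.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @param threshold Threshold for the binary metrics (default 0.5).
#' @return One-row tibble with `aupr`, `auc`, `f1`, `acc`, `rec`, `spec`,
#'   `pre`, `threshold`.
#' @examples
#' compute_metrics(c(.9, .8, .7, .6), c(1, 0, 1, 0))
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  assert_that(length(scores) == length(labels), "scores/labels length mismatch")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0, "need at least one positive and one negative")
  assert_that(all(is.finite(scores)), "non-finite scores")

  r <- rank(scores)  # average ranks = tie correction
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(-scores, seq_along(scores))  # ties -> lower original index
  y <- labels[ord]
  tp <- cumsum(y)
  prec_at <- tp / seq_along(y)
  aupr <- sum(prec_at[y == 1]) / n1  # step-wise average precision

  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1); FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0); FN <- sum(pred == 0 & labels == 1)
  rec <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  pre <- if (TP + FP > 0) TP / (TP + FP) else 0
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  acc <- (TP + TN) / length(labels)

  tibble::tibble(aupr = aupr, auc = auc, f1 = f1, acc = acc, rec = rec,
                 spec = spec, pre = pre, threshold = threshold)
}

#' Precision and recall among the top-K ranked predictions
#'
#' Ranks pairs by descending score (ties broken by original pair index) and
#' reports, for each cutoff K, the precision `TP/K` and recall
#' `TP/total positives`.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @param k_values Integer cutoffs, e.g. `seq(100, 1000, by = 100)`.
#' @return Tibble with `k`, `precision`, `recall`.
#' @export
topk_precision_recall <- function(scores, labels, k_values) {
  assert_that(length(k_values) > 0, "k_values must be non-empty")
  assert_that(all(k_values >= 1 & k_values <= length(scores)),
              "every K must be between 1 and the number of scored pairs")
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  tp <- cumsum(y)
  n1 <- sum(labels == 1)
  tibble::tibble(k = as.integer(k_values),
                 precision = tp[k_values] / k_values,
                 recall = tp[k_values] / n1)
}

#' Plot a top-K precision/recall table
#'
#' @param object Tibble from [topk_precision_recall()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_topk <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("precision", "recall"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "top K predictions", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
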