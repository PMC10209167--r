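#' Matthews correlation coefficient
#'
#' Balanced binary-classification score in \[-1, 1\]; defined as 0 when the
#' denominator vanishes (degenerate predictions or labels).
#'
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels.
#' @return numeric scalar.
#' @export
mcc <- function(pred, truth) {
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 with class 1 as the positive class
#' (set `positive = 0` for the per-class view of the negative class).
#' Undefined ratios (empty denominators) are reported as `NA`.
#'
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels.
#' @param positive which label counts as the positive class.
#' @return named numeric vector (accuracy, precision, recall, f1, mcc, n).
#' @export
classification_metrics <- function(pred, truth, positive = 1) {
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  p <- pred == positive
  t <- truth == positive
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(accuracy = mean(pred == truth), precision = precision, recall = recall,
    f1 = f1, mcc = mcc(pred, truth), n = length(truth))
}
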