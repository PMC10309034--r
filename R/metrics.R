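#' Confusion counts at a decision threshold
#'
#' A sample is predicted positive (malignant) when its probability is
#' strictly above `threshold`; `p == threshold` therefore predicts negative.
#'
#' @param labels true labels in `{0, 1}`.
#' @param probs predicted probabilities.
#' @param threshold decision threshold, default 0.5.
#' @return named integer vector `(TP, FP, TN, FN)`.
#' @export
confusionCounts <- function(labels, probs, threshold = 0.5) {
  stopifnot(length(labels) == length(probs), all(labels %in% c(0, 1)))
  pred <- as.integer(probs > threshold)
  c(TP = sum(pred == 1L & labels == 1L),
    FP = sum(pred == 1L & labels == 0L),
    TN = sum(pred == 0L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' F1 `2*Pre*Rec/(Pre+Rec)`. A metric whose denominator is zero is defined
#' as 0 (so a classifier that never predicts positive has precision 0, and
#' F1 is 0 whenever precision + recall is 0).
#'
#' @param counts named vector with `TP`, `FP`, `TN`, `FN` (order free).
#' @return an [EvalReport-class].
#' @examples
#' computeMetrics(c(TP = 3, FP = 1, TN = 5, FN = 1)) # Acc 0.8, others 0.75
#' @export
computeMetrics <- function(counts) {
  counts <- counts[c("TP", "FP", "TN", "FN")]
  if (any(is.na(counts))) stop("counts must contain TP, FP, TN, FN")
  counts <- as.integer(round(counts))
  if (any(counts < 0L)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0L) stop("no evaluated samples")
  tp <- counts[1L]; fp <- counts[2L]; tn <- counts[3L]; fn <- counts[4L]
  acc <- (tp + tn) / total
  pre <- if (tp + fp > 0L) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  new("EvalReport", accuracy = acc, precision = pre, recall = rec, f1 = f1,
      counts = stats::setNames(counts, c("TP", "FP", "TN", "FN")))
}
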