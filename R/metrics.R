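# Evaluation metrics: accuracy from a binary confusion table and mean
# binary cross-entropy with clipped predictions.

#' Build a binary confusion table at the 0.5 threshold
#'
#' @param y actual 0/1 labels.
#' @param prob predicted probabilities.
#' @param threshold decision threshold (default 0.5; predictions >= the
#'   threshold are called positive).
#' @return list with integer counts `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y, prob, threshold = 0.5) {
  stopifnot(length(y) == length(prob), all(y %in% c(0, 1)))
  pred <- as.integer(prob >= threshold)
  list(TP = sum(pred == 1L & y == 1), TN = sum(pred == 0L & y == 0),
       FP = sum(pred == 1L & y == 0), FN = sum(pred == 0L & y == 1))
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts list with elements TP, TN, FP, FN (non-negative).
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (length(total) != 1L || !is.finite(total) || total < 1)
    stop("accuracy is undefined for an empty confusion table", call. = FALSE)
  (counts$TP + counts$TN) / total
}

#' Mean binary cross-entropy
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))` with natural logs;
#' predictions are clipped to `[eps, 1 - eps]` first.
#'
#' @param y actual 0/1 labels.
#' @param prob predicted probabilities.
#' @param eps clipping constant (default 1e-7).
#' @return non-negative scalar.
#' @export
cross_entropy <- function(y, prob, eps = 1e-7) {
  if (length(y) != length(prob))
    stop("labels and predictions differ in length (", length(y), " vs ",
         length(prob), ")", call. = FALSE)
  stopifnot(length(y) >= 1, all(y %in% c(0, 1)))
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
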