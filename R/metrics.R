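# Binary classification metrics: accuracy, F1 and rank-based ROC AUC.

#' Confusion counts for binary predictions
#'
#' @param truth true 0/1 labels.
#' @param predicted predicted 0/1 labels.
#' @return list with integer fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- check_labels(truth, length(truth), FALSE)
  predicted <- check_labels(predicted, length(predicted), FALSE)
  if (length(truth) != length(predicted)) stop("length mismatch")
  list(TP = sum(truth == 1L & predicted == 1L),
       TN = sum(truth == 0L & predicted == 0L),
       FP = sum(truth == 0L & predicted == 1L),
       FN = sum(truth == 1L & predicted == 0L))
}

#' Accuracy from confusion counts
#'
#' The proportion of correct predictions, `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts a list with fields `TP`, `TN`, `FP`, `FN`
#'   (see [confusion_counts()]).
#' @return value in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total <= 0) stop("no predictions: all confusion counts are zero")
  (counts$TP + counts$TN) / total
}

#' F1 score from confusion counts
#'
#' Harmonic mean of precision `TP / (TP + FP)` and recall `TP / (TP + FN)`;
#' defined as 0 (with a warning) when there are no true positives.
#'
#' @inheritParams accuracy
#' @return value in `[0, 1]`.
#' @export
f1 <- function(counts) {
  if (counts$TP + counts$FP + counts$FN <= 0) {
    warning("F1 undefined (no positive labels or predictions); returning 0")
    return(0)
  }
  if (counts$TP == 0) return(0)
  precision <- counts$TP / (counts$TP + counts$FP)
  recall <- counts$TP / (counts$TP + counts$FN)
  2 * precision * recall / (precision + recall)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie correction: the
#' probability that a random positive sample scores above a random negative
#' one, ties counted one half.
#'
#' @param scores per-sample real scores (probabilities or margins; any
#'   monotone scale).
#' @param y true 0/1 labels; both classes must be present.
#' @return value in `[0, 1]`.
#' @export
roc_auc <- function(scores, y) {
  y <- check_labels(y, length(scores), FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("ROC AUC requires both classes")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Accuracy, F1 and ROC AUC from predicted probabilities
#'
#' @param truth true 0/1 labels.
#' @param prob predicted class-1 probabilities; classes are assigned at 0.5.
#' @return named numeric vector `c(accuracy, f1, roc_auc)`.
#' @export
classification_metrics <- function(truth, prob) {
  cc <- confusion_counts(truth, as.integer(prob >= 0.5))
  c(accuracy = accuracy(cc), f1 = f1(cc), roc_auc = roc_auc(prob, truth))
}
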