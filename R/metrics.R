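# Evaluation metrics over confusion matrices (rows = truth, cols = predicted).

#' Build a confusion matrix
#'
#' @param truth,predicted Vectors of class labels of equal length.
#' @param classes Optional class ordering; defaults to the sorted union.
#' @return Square count matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(as.character(truth),
                                                 as.character(predicted))))
  t_ <- factor(as.character(truth), levels = classes)
  p_ <- factor(as.character(predicted), levels = classes)
  unclass(table(truth = t_, predicted = p_))
}

check_confusion <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  if (any(confusion < 0)) stop("confusion matrix has negative entries")
  if (sum(confusion) == 0) stop("undefined metric: all-zero confusion matrix")
}

safe_ratio <- function(num, den, what) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0))
    warning(what, " undefined for class(es) with zero denominator; set to 0")
  out
}

#' Balanced accuracy (mean per-class recall)
#'
#' @param confusion Square count matrix, rows = truth, cols = predicted.
#' @return Value in `[0, 1]`.
#' @export
balanced_accuracy <- function(confusion) {
  check_confusion(confusion)
  recall <- safe_ratio(diag(confusion), rowSums(confusion), "recall")
  mean(recall)
}

#' Precision-based binary balanced accuracy
#'
#' The as-printed binary variant `(TP/(TP+FP) + TN/(TN+FN)) / 2`, which
#' averages the two predictive values rather than the two recalls. Provided
#' for comparison; [balanced_accuracy()] (mean recall) is the default metric
#' everywhere else.
#'
#' @param confusion 2x2 count matrix with the positive class first
#'   (`TP = [1,1]`, `FN = [1,2]`, `FP = [2,1]`, `TN = [2,2]`).
#' @return Value in `[0, 1]`.
#' @export
balanced_accuracy_printed <- function(confusion) {
  check_confusion(confusion)
  stopifnot(nrow(confusion) == 2)
  tp <- confusion[1, 1]; fn <- confusion[1, 2]
  fp <- confusion[2, 1]; tn <- confusion[2, 2]
  ppv <- safe_ratio(tp, tp + fp, "positive predictive value")
  npv <- safe_ratio(tn, tn + fn, "negative predictive value")
  (ppv + npv) / 2
}

#' Matthews correlation coefficient
#'
#' Multiclass (Gorodkin) generalization; reduces to
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` for 2x2 input.
#'
#' @inheritParams balanced_accuracy
#' @return Value in `[-1, 1]`.
#' @export
mcc <- function(confusion) {
  check_confusion(confusion)
  c_ <- sum(diag(confusion))
  s <- sum(confusion)
  p <- colSums(confusion)
  t_ <- rowSums(confusion)
  num <- c_ * s - sum(p * t_)
  den2 <- (s^2 - sum(p^2)) * (s^2 - sum(t_^2))
  if (den2 <= 0) {
    warning("MCC undefined (degenerate margins); set to 0")
    return(0)
  }
  num / sqrt(den2)
}

#' F1 score
#'
#' Per-class F1 is the harmonic mean of precision and recall; multiclass
#' aggregation is support-weighted by default, macro-averaged or per-class
#' on request.
#'
#' @inheritParams balanced_accuracy
#' @param average `"weighted"` (default), `"macro"`, or `"none"` for the
#'   per-class vector.
#' @return Value in `[0, 1]`, or a named per-class vector.
#' @export
f1_score <- function(confusion, average = c("weighted", "macro", "none")) {
  average <- match.arg(average)
  check_confusion(confusion)
  precision <- safe_ratio(diag(confusion), colSums(confusion), "precision")
  recall <- safe_ratio(diag(confusion), rowSums(confusion), "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  names(f1) <- rownames(confusion)
  switch(average,
         none = f1,
         macro = mean(f1),
         weighted = {
           w <- rowSums(confusion)
           sum(f1 * w) / sum(w)
         })
}
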