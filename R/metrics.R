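# Confusion matrix and one-vs-rest classification metrics.

#' Confusion matrix from predicted and true labels
#'
#' @param predictions Integer vector of predicted class labels in `[0, K)`.
#' @param labels Integer vector of true class labels in `[0, K)`; same
#'   length as `predictions`.
#' @param num_classes Number of classes K.
#' @return A K x K integer matrix of counts; rows index the true class,
#'   columns the predicted class.
#' @examples
#' compute_confusion(c(0, 1, 1, 1), c(0, 0, 1, 1), 2)
#' @export
compute_confusion <- function(predictions, labels, num_classes) {
  num_classes <- as.integer(num_classes)
  stopifnot(num_classes >= 1L)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have the same length")
  }
  if (length(labels) &&
      (any(predictions < 0 | predictions >= num_classes) ||
       any(labels < 0 | labels >= num_classes))) {
    stop(sprintf("labels must lie in [0, %d)", num_classes))
  }
  lv <- 0:(num_classes - 1L)
  cm <- table(factor(labels, levels = lv), factor(predictions, levels = lv))
  m <- matrix(as.integer(cm), num_classes, num_classes,
              dimnames = list(true = lv, predicted = lv))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Accuracy, precision and recall from a confusion matrix
#'
#' Accuracy is the trace over the total. Per class k (one-vs-rest):
#' `TP = cm[k,k]`, `FP = colsum_k - TP`, `FN = rowsum_k - TP`;
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`, with 0
#' substituted (and the class flagged as degenerate) when a denominator is
#' zero. Averaged values are unweighted (macro) by default; `"weighted"`
#' weights each class by its true-label support.
#'
#' @param cm A square confusion matrix (rows true, columns predicted) with a
#'   positive total.
#' @param average `"macro"` (default) or `"weighted"`.
#' @return A list of class `metrics_report` with fields `accuracy`,
#'   `per_class_precision`, `per_class_recall`, `macro_precision`,
#'   `macro_recall`, and logical vectors `degenerate_precision` /
#'   `degenerate_recall` marking zero-denominator classes.
#' @examples
#' compute_metrics(compute_confusion(c(0, 1, 1, 1), c(0, 0, 1, 1), 2))
#' @export
compute_metrics <- function(cm, average = c("macro", "weighted")) {
  average <- match.arg(average)
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("cm must be a square matrix")
  }
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix total must be positive")
  tp <- diag(cm)
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  deg_p <- colsum == 0
  deg_r <- rowsum == 0
  precision <- ifelse(deg_p, 0, tp / pmax(colsum, 1e-300))
  recall <- ifelse(deg_r, 0, tp / pmax(rowsum, 1e-300))
  w <- if (average == "macro") {
    rep(1 / nrow(cm), nrow(cm))
  } else {
    rowsum / total
  }
  structure(list(accuracy = sum(tp) / total,
                 per_class_precision = as.numeric(precision),
                 per_class_recall = as.numeric(recall),
                 macro_precision = sum(w * precision),
                 macro_recall = sum(w * recall),
                 degenerate_precision = as.logical(deg_p),
                 degenerate_recall = as.logical(deg_r),
                 average = average),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy: %.4f  %s precision: %.4f  %s recall: %.4f\n",
              x$accuracy, x$average, x$macro_precision, x$average,
              x$macro_recall))
  if (any(x$degenerate_precision) || any(x$degenerate_recall)) {
    cat("note: zero-denominator classes reported as 0 (degenerate)\n")
  }
  invisible(x)
}
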