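# Classification metrics: confusion matrices, one-vs-rest Dice and Matthews
# coefficients, fold averaging.

#' Confusion matrix
#'
#' @param predictions,truths equal-length integer vectors of 0-based class
#'   labels.
#' @param n_classes number of classes.
#' @return n_classes x n_classes integer matrix; entry (i, j) counts samples
#'   of true class i-1 predicted as class j-1.
#' @export
confusion_matrix <- function(predictions, truths, n_classes) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length")
  }
  if (any(c(predictions, truths) < 0 | c(predictions, truths) >= n_classes)) {
    stop("label out of range")
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(truth = 0:(n_classes - 1),
                               predicted = 0:(n_classes - 1)))
  for (i in seq_along(truths)) {
    cm[truths[i] + 1L, predictions[i] + 1L] <-
      cm[truths[i] + 1L, predictions[i] + 1L] + 1L
  }
  cm
}

#' One-vs-rest counts for one class
#'
#' @param cm a [confusion_matrix()].
#' @param class 0-based class index.
#' @return list with `TP`, `FP`, `FN`, `TN` (they sum to the sample count).
#' @export
class_counts <- function(cm, class) {
  k <- class + 1L
  tp <- cm[k, k]
  fp <- sum(cm[-k, k])
  fn <- sum(cm[k, -k])
  tn <- sum(cm) - tp - fp - fn
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Dice similarity coefficient
#'
#' DSC = 2 TP / (2 TP + FP + FN).
#'
#' @param counts a [class_counts()] list.
#' @return DSC in [0, 1]; `NA` with a warning when the denominator is zero.
#' @export
dice <- function(counts) {
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) {
    warning("Dice undefined: no samples involve this class")
    return(NA_real_)
  }
  2 * counts$TP / den
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); 0 by
#' convention (with a warning) when any factor of the denominator vanishes.
#'
#' @param counts a [class_counts()] list.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  fn <- as.numeric(counts$FN); tn <- as.numeric(counts$TN)
  facs <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(facs == 0)) {
    warning("MCC denominator degenerate; returning 0 by convention")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(prod(facs))
}

#' Per-fold metric report from cross-validation results
#'
#' Computes, on each fold's validation split, the confusion matrix and the
#' one-vs-rest DSC and MCC of every class.
#'
#' @param kfold a [kfold_train()] result.
#' @param n_classes number of classes.
#' @param class_names optional labels for reporting.
#' @return list of per-fold lists (`cm`, `dsc`, `mcc`).
#' @export
fold_metrics <- function(kfold, n_classes,
                         class_names = as.character(0:(n_classes - 1))) {
  lapply(kfold, function(fr) {
    cm <- confusion_matrix(fr$val_pred, fr$val_truth, n_classes)
    counts <- lapply(0:(n_classes - 1), function(c) class_counts(cm, c))
    list(cm = cm,
         dsc = stats::setNames(vapply(counts, dice, numeric(1)),
                               class_names),
         mcc = stats::setNames(vapply(counts, mcc, numeric(1)),
                               class_names))
  })
}

#' Fold-averaged metric report
#'
#' Arithmetic mean of each per-class metric over folds, plus the aggregated
#' (summed) confusion matrix, misclassification count/rate, and overall
#' validation accuracy.
#'
#' @param per_fold a [fold_metrics()] result (>= 1 fold).
#' @return object of class `metric_report`: `metrics` (data.frame with
#'   class, dsc, mcc), `confusion` (summed matrix), `n_val`,
#'   `misclassified`, `misclassification_rate`, `accuracy`.
#' @export
fold_average <- function(per_fold) {
  stopifnot(length(per_fold) >= 1)
  classes <- names(per_fold[[1]]$dsc)
  for (fr in per_fold) {
    if (!identical(names(fr$dsc), classes)) {
      stop("fold reports have mismatched class sets")
    }
  }
  dsc <- colMeans(do.call(rbind, lapply(per_fold, `[[`, "dsc")))
  mcc_m <- colMeans(do.call(rbind, lapply(per_fold, `[[`, "mcc")))
  cm <- Reduce(`+`, lapply(per_fold, `[[`, "cm"))
  n <- sum(cm)
  mis <- n - sum(diag(cm))
  structure(list(
    metrics = data.frame(class = classes, dsc = as.numeric(dsc),
                         mcc = as.numeric(mcc_m)),
    confusion = cm, n_val = n, misclassified = mis,
    misclassification_rate = mis / n, accuracy = 1 - mis / n),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Validation metrics (fold-averaged; %d samples, accuracy %.3f, misclassified %.1f%%)\n",
              x$n_val, x$accuracy, 100 * x$misclassification_rate))
  print(x$metrics, row.names = FALSE)
  cat("Aggregated confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat("Note: MCC tends to report lower values than DSC.\n")
  invisible(x)
}
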