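#' Confusion matrix for the two-class problem
#'
#' Rows are actual classes, columns predicted classes, both ordered
#' `(barnyard_grass, rice)`. Barnyard grass is the positive class, so
#' `TP = [1,1]`, `FN = [1,2]`, `FP = [2,1]`, `TN = [2,2]`.
#'
#' @param y_true Actual labels (factor or character).
#' @param y_pred Predicted labels.
#' @return Integer 2x2 matrix with dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  lv <- spectra_classes()
  y_true <- factor(as.character(y_true), levels = lv)
  y_pred <- factor(as.character(y_pred), levels = lv)
  if (anyNA(y_true) || anyNA(y_pred)) stop("labels outside the two classes")
  m <- table(actual = y_true, predicted = y_pred)
  matrix(as.integer(m), 2, 2, dimnames = list(actual = lv, predicted = lv))
}

#' Classification accuracy from a confusion matrix
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param confusion 2x2 count matrix as returned by [confusion_matrix()].
#' @return Fraction correct in `[0, 1]`.
#' @export
accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n == 0) stop("empty confusion matrix")
  sum(diag(confusion)) / n
}

#' Matthews correlation coefficient
#'
#' The standard product form
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`, a balanced
#' summary in `[-1, 1]`. When any factor of the denominator is zero (only
#' one class present or predicted) the coefficient is defined as 0, the
#' usual convention for the degenerate case.
#'
#' @param confusion 2x2 count matrix as returned by [confusion_matrix()].
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(confusion) {
  confusion <- as.matrix(confusion)
  tp <- confusion[1, 1]; fn <- confusion[1, 2]
  fp <- confusion[2, 1]; tn <- confusion[2, 2]
  den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' ROC curve and AUC from positive-class scores
#'
#' The AUC is computed as the normalized Mann-Whitney U statistic: the
#' probability that a random positive scores above a random negative, with
#' ties counting one half. ROC points come from sweeping the decision
#' threshold over the distinct scores.
#'
#' @param y_true Actual labels; both classes must be present.
#' @param scores Numeric scores (e.g. predicted probabilities) for the
#'   positive class, barnyard grass.
#' @return List with `auc` and `roc_points` (data.frame of `fpr`, `tpr`
#'   ordered by increasing false-positive rate).
#' @export
roc_auc <- function(y_true, scores) {
  lv <- spectra_classes()
  y <- factor(as.character(y_true), levels = lv)
  if (anyNA(y)) stop("labels outside the two classes")
  if (length(y) != length(scores)) stop("length mismatch")
  pos <- y == lv[1]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  # Mann-Whitney U via midranks; ties contribute 1/2
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # threshold sweep: predict positive when score >= t
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(ths, function(t) {
    pred_pos <- scores >= t
    c(fpr = sum(pred_pos & !pos) / n_neg, tpr = sum(pred_pos & pos) / n_pos)
  }, numeric(2)))
  list(auc = auc, roc_points = as.data.frame(pts))
}

#' Full evaluation report
#'
#' Bundles the confusion matrix, accuracy, MCC and (when scores are given)
#' the ROC curve with its AUC into a single object.
#'
#' @param y_true Actual labels.
#' @param y_pred Predicted labels.
#' @param scores Optional positive-class scores for the ROC/AUC.
#' @return An `EvalReport` list with elements `confusion`, `acc`, `mcc`,
#'   and optionally `auc` and `roc_points`.
#' @export
eval_report <- function(y_true, y_pred, scores = NULL) {
  cm <- confusion_matrix(y_true, y_pred)
  rep <- list(confusion = cm, acc = accuracy(cm), mcc = mcc(cm))
  if (!is.null(scores)) {
    ra <- roc_auc(y_true, scores)
    rep$auc <- ra$auc
    rep$roc_points <- ra$roc_points
  }
  structure(rep, class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("Confusion matrix (rows = actual, cols = predicted):\n")
  print(x$confusion)
  cat(sprintf("ACC = %.4f  MCC = %.4f", x$acc, x$mcc))
  if (!is.null(x$auc)) cat(sprintf("  AUC = %.4f", x$auc))
  cat("\n")
  invisible(x)
}
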