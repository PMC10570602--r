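#' Confusion counts for binary predictions
#'
#' Class 1 is the positive class.
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return an object of class `confusion_counts` with fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (!length(y_true)) stop("empty input")
  if (!all(y_true %in% 0:1) || !all(y_pred %in% 0:1))
    stop("labels and predictions must be 0/1")
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == 0),
    TN = sum(y_true == 0 & y_pred == 0)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + FP + FN + TN)`.
#'
#' @param cc a `confusion_counts` object.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(cc) {
  total <- cc$TP + cc$FP + cc$FN + cc$TN
  if (total < 1) stop("empty confusion counts")
  (cc$TP + cc$TN) / total
}

#' F1 score
#'
#' `2 TP / (2 TP + FN + FP)`. When no positives exist anywhere
#' (denominator 0) the score is defined as 0 with a warning.
#'
#' @param cc a `confusion_counts` object.
#' @return F1 in `[0, 1]`.
#' @export
f1 <- function(cc) {
  den <- 2 * cc$TP + cc$FN + cc$FP
  if (den < 1) {
    warning("F1 undefined (no positives predicted or observed); returning 0")
    return(0)
  }
  2 * cc$TP / den
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, counting ties as one half. Equal to the trapezoidal area
#' under the ROC curve and invariant under strictly monotone score
#' transforms.
#'
#' @param y_true 0/1 vector with both classes present.
#' @param scores real score vector (larger = more positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    stop("y_true and scores must have the same length")
  npos <- sum(y_true == 1); nneg <- sum(y_true == 0)
  if (npos == 0 || nneg == 0)
    stop("AUC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic on an `R x C` contingency table:
#' `sum((O - E)^2 / E)` with `E = row_sum * col_sum / total` and
#' `df = (R - 1)(C - 1)`. No continuity correction is applied.
#'
#' @param counts non-negative integer matrix with `R, C >= 2` and strictly
#'   positive row and column sums.
#' @return `list(statistic, df, p_value)`.
#' @examples
#' # association of gender with depression status in a 3-wave Chinese
#' # middle-aged/elderly survey panel (rows male/female, cols case/control)
#' pearson_chi2(matrix(c(384, 1284, 871, 1348), 2, byrow = TRUE))
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0) || anyNA(counts))
    stop("counts must be non-negative and complete")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("all row and column sums must be positive")
  total <- sum(counts)
  expected <- outer(rs, cs) / total
  statistic <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE))
}
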