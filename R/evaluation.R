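# Classification metrics: confusion counts, ACC/SEN/SPE, ROC and AUC.
# The positive class is AB (abnormal, label 1) throughout, which fixes the
# orientation of sensitivity and specificity.

#' Confusion counts of a binary prediction
#'
#' @param labels Integer 0/1 truth vector (1 = AB, the positive class).
#' @param predictions Integer 0/1 predictions, same length.
#' @return A `confusion_counts` object: named vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels (", length(labels), ") and predictions (",
         length(predictions), ") differ in length")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop("labels and predictions must be binary 0/1")
  out <- c(TP = sum(labels == 1 & predictions == 1),
           TN = sum(labels == 0 & predictions == 0),
           FP = sum(labels == 0 & predictions == 1),
           FN = sum(labels == 1 & predictions == 0))
  structure(as.integer(out), names = names(out), class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity
#'
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, `SEN = TP / (TP + FN)`,
#' `SPE = TN / (FP + TN)`.  A zero denominator raises an error naming the
#' undefined indicator.
#'
#' @param counts A [confusion_counts()] object or named vector with
#'   elements `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `c(ACC, SEN, SPE)`, each in `[0, 1]`.
#' @export
acc_sen_spe <- function(counts) {
  cc <- counts[c("TP", "TN", "FP", "FN")]
  if (anyNA(cc)) stop("counts must contain TP, TN, FP, FN")
  if (any(cc < 0)) stop("counts must be non-negative")
  tot <- sum(cc)
  if (tot < 1) stop("ACC undefined: no observations")
  if (cc["TP"] + cc["FN"] == 0) stop("SEN undefined: TP + FN = 0")
  if (cc["FP"] + cc["TN"] == 0) stop("SPE undefined: FP + TN = 0")
  c(ACC = unname((cc["TP"] + cc["TN"]) / tot),
    SEN = unname(cc["TP"] / (cc["TP"] + cc["FN"])),
    SPE = unname(cc["TN"] / (cc["FP"] + cc["TN"])))
}

#' ROC curve by full threshold sweep
#'
#' Sweeps all distinct score values as decision thresholds (predict AB when
#' `score >= threshold`), grouping tied scores at one threshold.  The curve
#' starts at (0, 0) and ends at (1, 1); `TPR = TP / (TP + FN)` and
#' `FPR = FP / (FP + TN)`.
#'
#' @param scores Numeric scores, larger = more AB-like.
#' @param labels Integer 0/1 truth vector; both classes must be present.
#' @return A `roc_curve`: data frame with `threshold`, `FPR`, `TPR`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  nP <- sum(labels == 1); nN <- sum(labels == 0)
  if (nP == 0 || nN == 0)
    stop("ROC undefined: need at least one positive and one negative label")
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("scores must be finite")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  thr <- unique(s)
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- cumsum(table(factor(s, levels = thr)))  # index of last tie per thr
  df <- data.frame(threshold = c(Inf, thr),
                   FPR = c(0, fp[last] / nN),
                   TPR = c(0, tp[last] / nP))
  rownames(df) <- NULL
  structure(df, class = c("roc_curve", "data.frame"))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of a [roc_curve()]; equivalently accepts raw
#' scores and labels.  Equals the Mann-Whitney concordance probability with
#' half-credit for ties.
#'
#' @param x A `roc_curve`, or numeric scores.
#' @param labels Required when `x` is a score vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(x, labels = NULL) {
  if (!inherits(x, "roc_curve")) {
    if (is.null(labels)) stop("labels required when x is a score vector")
    x <- roc_curve(x, labels)
  }
  sum(diff(x$FPR) * (utils::head(x$TPR, -1) + utils::tail(x$TPR, -1)) / 2)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$FPR, x$TPR, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x["TP"], x["FN"], x["FP"], x["TN"]), 2, 2,
              dimnames = list(c("pred AB", "pred HC"),
                              c("true AB", "true HC")))
  print(m)
  invisible(x)
}
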