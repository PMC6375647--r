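#' One-vs-rest confusion counts
#'
#' @param truth True labels.
#' @param predicted Predicted labels (same length).
#' @param positive The label treated as the positive class.
#' @return A `confusion_counts` vector with elements TP, TN, FP, FN.
#' @export
confusion <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stopf("truth and predicted must have equal length")
  tpos <- truth == positive
  ppos <- predicted == positive
  structure(c(TP = sum(tpos & ppos), TN = sum(!tpos & !ppos),
              FP = sum(!tpos & ppos), FN = sum(tpos & !ppos)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy ACC = (TP + TN) / (TP + FP + TN + FN), precision
#' PPV = TP / (TP + FP), specificity TNR = TN / (TN + FP), sensitivity
#' TPR = TP / (TP + FN), and fall-out FPR = FP / (FP + TN).  A metric whose
#' denominator is zero is reported as `NA` (undefined), never coerced to 0.
#'
#' @param c A `confusion_counts` vector (or any vector with names TP, TN,
#'   FP, FN).
#' @return Named numeric vector ACC, PPV, TNR, TPR, FPR.
#' @export
classification_metrics <- function(c) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tp <- c[["TP"]]; tn <- c[["TN"]]; fp <- c[["FP"]]; fn <- c[["FN"]]
  c(ACC = ratio(tp + tn, tp + fp + tn + fn),
    PPV = ratio(tp, tp + fp),
    TNR = ratio(tn, tn + fp),
    TPR = ratio(tp, tp + fn),
    FPR = ratio(fp, fp + tn))
}

#' Matthews correlation coefficient
#'
#' `MCC = (TN * TP - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' ranging from -1 (perfect anti-correlation) through 0 (random) to 1
#' (perfect classification).  Undefined (`NA`) when any marginal is zero.
#'
#' @inheritParams classification_metrics
#' @return A number in \[-1, 1\], or `NA`.
#' @export
mcc <- function(c) {
  tp <- c[["TP"]]; tn <- c[["TN"]]; fp <- c[["FP"]]; fn <- c[["FN"]]
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(NA_real_)
  (tn * tp - fp * fn) / sqrt(den)
}

#' ROC curve and AUC
#'
#' Sweeps the unique score values as decision thresholds (ties grouped at
#' one threshold), accumulating (FPR, TPR) points from (0, 0) to (1, 1),
#' and integrates the curve with the trapezoidal rule.  The resulting AUC
#' equals the Mann-Whitney pair statistic with ties counted 1/2.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Logical (or coercible) positive-class indicator.
#' @return List with `curve` (data frame threshold, FPR, TPR) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    stopf("ROC requires both classes present (got %d positive, %d negative)",
          np, nn)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  last <- which(!duplicated(s, fromLast = TRUE))
  # cumulative counts at each distinct threshold (all ties included)
  ctp <- cumsum(l); cfp <- cumsum(!l)
  tpr <- c(0, ctp[last] / np)
  fpr <- c(0, cfp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(threshold = c(Inf, s[last]), FPR = fpr, TPR = tpr),
       auc = auc)
}
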