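# Confusion-matrix metrics and ROC/AUC. Malignant is the positive class
# throughout: TP/FN count correctly/incorrectly classified malignant cases,
# TN/FP the benign ones.

#' Confusion matrix
#'
#' @param TP,FN Correctly / incorrectly classified malignant (positive)
#'   cases.
#' @param TN,FP Correctly / incorrectly classified benign (negative) cases.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FN, TN, FP) {
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (malignant = positive):\n")
  cat("  TP =", x$TP, " FN =", x$FN, "\n  FP =", x$FP, " TN =", x$TN, "\n")
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Evaluates accuracy, sensitivity, specificity, positive and negative
#' predictive value, and Matthew's correlation coefficient:
#' \deqn{ACC = (TP+TN)/n,\; SENS = TP/(TP+FN),\; SPEC = TN/(TN+FP),}
#' \deqn{PPV = TP/(TP+FP),\; NPV = TN/(TN+FN),}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' Any metric whose denominator is zero is reported as `NA` (undefined),
#' never silently as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class `eval_report` with fields `acc`, `sens`, `spec`,
#'   `ppv`, `npv`, `mcc` (proportions in \[0,1\], MCC in \[-1,1\]), `auc`
#'   (`NA`; filled by score-based evaluators) and `confusion`.
#' @examples
#' confusion_metrics(confusion_matrix(TP = 60, FN = 9, TN = 60, FP = 9))
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP; FN <- cm$FN; TN <- cm$TN; FP <- cm$FP
  if (TP + FN == 0 || TN + FP == 0) {
    stop("need at least one positive and one negative case")
  }
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  structure(
    list(auc = NA_real_,
         acc = safe_div(TP + TN, TP + TN + FP + FN),
         sens = safe_div(TP, TP + FN),
         spec = safe_div(TN, TN + FP),
         ppv = safe_div(TP, TP + FP),
         npv = safe_div(TN, TN + FN),
         mcc = if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den,
         confusion = cm),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(v, digits = 4, format = "f"))
  cat("AUC = ", fmt(x$auc), ", ACC = ", fmt(x$acc),
      ", SENS = ", fmt(x$sens), ", SPEC = ", fmt(x$spec), "\n",
      "PPV = ", fmt(x$ppv), ", NPV = ", fmt(x$npv),
      ", MCC = ", fmt(x$mcc), "\n", sep = "")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC of decision scores against binary labels; equals the
#' probability that a random malignant case outscores a random benign one,
#' ties counted one half. Invariant under any strictly increasing transform
#' of the scores.
#'
#' @param scores Numeric decision values, higher favoring malignant.
#' @param labels Vector with two classes; interpreted via [as_label_factor()]
#'   (malignant = positive).
#' @return Scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  lab <- as_label_factor(labels)
  if (length(unique(lab)) < 2) stop("both classes must be present")
  stopifnot(length(scores) == length(lab), all(is.finite(scores)))
  as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = as.numeric(scores),
    levels = c("benign", "malignant"), direction = "<", quiet = TRUE
  )))
}

#' ROC curve coordinates
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr` (1 - specificity) and `tpr`
#'   (sensitivity), ordered along the curve.
#' @export
roc_curve <- function(scores, labels) {
  lab <- as_label_factor(labels)
  r <- pROC::roc(response = lab, predictor = as.numeric(scores),
                 levels = c("benign", "malignant"), direction = "<",
                 quiet = TRUE)
  tibble::tibble(threshold = rev(r$thresholds),
                 fpr = rev(1 - r$specificities),
                 tpr = rev(r$sensitivities))
}

#' Normalize class labels to a benign/malignant factor
#'
#' Accepts a factor or character vector with levels `benign`/`malignant`
#' (any case), or 0/1 with 1 = malignant.
#'
#' @param labels Vector of class labels.
#' @return Factor with levels `c("benign", "malignant")`.
#' @export
as_label_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels) || is.logical(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    labels <- ifelse(as.numeric(labels) == 1, "malignant", "benign")
  }
  labels <- tolower(labels)
  if (!all(labels %in% c("benign", "malignant"))) {
    stop("labels must be 'benign' or 'malignant' (or 0/1)")
  }
  factor(labels, levels = c("benign", "malignant"))
}

# report from pooled held-out scores: threshold at 0, AUC from the scores
report_from_scores <- function(scores, labels, threshold = 0) {
  lab <- as_label_factor(labels)
  pred_mal <- scores > threshold
  cm <- confusion_matrix(
    TP = sum(pred_mal & lab == "malignant"),
    FN = sum(!pred_mal & lab == "malignant"),
    TN = sum(!pred_mal & lab == "benign"),
    FP = sum(pred_mal & lab == "benign")
  )
  rep <- confusion_metrics(cm)
  rep$auc <- roc_auc(scores, lab)
  rep
}
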