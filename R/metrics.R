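# Confusion counts, the published metric set (including the "Spec" column
# that is numerically precision), ROC/AUC, and TP-versus-log10(FP) curves.

#' Confusion counts at a threshold
#'
#' A residue is called positive iff its score is >= `threshold`.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels, same length.
#' @param threshold Score cutoff.
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `tn`, `fn`, `threshold`.
#' @export
confusion_at <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  call_pos <- scores >= threshold
  pos <- labels == 1
  confusion_counts(tp = sum(call_pos & pos), fp = sum(call_pos & !pos),
                   tn = sum(!call_pos & !pos), fn = sum(!call_pos & pos),
                   threshold = threshold)
}

#' @rdname confusion_at
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn, threshold = NA_real_) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0))
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 tn = as.numeric(tn), fn = as.numeric(fn),
                 threshold = threshold),
            class = "confusion_counts")
}

#' Classification metric set
#'
#' Computes sensitivity TP/(TP+FN), precision TP/(TP+FP) (reported under
#' `spec_as_precision`, matching the published "Spec" column, which is
#' numerically precision), textbook specificity TN/(TN+FP), the Matthews
#' correlation coefficient, and accuracy as a percentage. A metric whose
#' denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param c A [confusion_counts()] object.
#' @param digits Rounding applied to the `rounded` element (2 matches the
#'   published tables); the `raw` element is unrounded.
#' @return List with `raw` and `rounded` named vectors: `sens`,
#'   `spec_as_precision`, `specificity`, `mcc`, `acc_percent`.
#' @export
metric_set <- function(c, digits = 2) {
  stopifnot(inherits(c, "confusion_counts"))
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  tp <- c$tp; fp <- c$fp; tn <- c$tn; fn <- c$fn
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  raw <- c(sens = sdiv(tp, tp + fn),
           spec_as_precision = sdiv(tp, tp + fp),
           specificity = sdiv(tn, tn + fp),
           mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
           acc_percent = sdiv(100 * (tp + tn), tp + fp + tn + fn))
  list(raw = raw, rounded = round(raw, digits))
}

#' ROC curve and AUC
#'
#' Thresholds sweep the unique score values (ties grouped at one
#' threshold); the area under the curve is computed by the trapezoidal
#' rule over (FPR, TPR) points, equivalent to the Mann-Whitney rank
#' statistic with ties counted half.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  P <- sum(labels == 1); Ng <- sum(labels == 0)
  if (P == 0 || Ng == 0) stop("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at each unique threshold (call at score >= threshold)
  keep <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y == 1)[keep]
  fp <- cumsum(y == 0)[keep]
  pts <- data.frame(threshold = s[keep], fpr = fp / Ng, tpr = tp / P)
  # prepend the all-negative point
  fpr <- c(0, pts$fpr); tpr <- c(0, pts$tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' True positives versus log10 false positives
#'
#' Raw TP and log10(FP) per threshold, for the heavily imbalanced regime
#' where false positives dwarf true positives. Thresholds with zero false
#' positives are reported with `log10_fp = -Inf` rather than dropped.
#'
#' @inheritParams roc_curve
#' @param thresholds Optional explicit threshold vector; defaults to the
#'   unique score values in decreasing order.
#' @return data.frame with `threshold`, `tp`, `fp`, `log10_fp`.
#' @export
tp_vs_log10fp <- function(scores, labels, thresholds = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (is.null(thresholds)) thresholds <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thresholds, function(t) sum(scores >= t & labels == 1), 0)
  fp <- vapply(thresholds, function(t) sum(scores >= t & labels == 0), 0)
  data.frame(threshold = thresholds, tp = tp, fp = fp,
             log10_fp = ifelse(fp == 0, -Inf, log10(fp)))
}
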