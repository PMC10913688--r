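## Evaluation protocol: confusion-matrix metrics (Sn, Sp, Acc, MCC),
## rank-based ROC-AUC, step-wise PR-AUC and F1.

#' Confusion counts at a decision threshold
#'
#' A sample is predicted positive iff its score is at least `threshold`
#' (default 0.5 on the positive-class probability).
#'
#' @param labels binary vector (1 = positive).
#' @param scores numeric vector in \[0, 1\], same length as `labels`.
#' @param threshold decision threshold.
#' @return `list(TP, TN, FP, FN)` of class `m5c_confusion`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  pred <- scores >= threshold
  pos <- labels == 1
  structure(list(TP = sum(pred & pos), TN = sum(!pred & !pos),
                 FP = sum(pred & !pos), FN = sum(!pred & pos),
                 threshold = threshold),
            class = "m5c_confusion")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any metric whose denominator is zero is reported as 0 so that reports
#' stay total on degenerate inputs.
#'
#' @param cc a [confusion_counts()] result, or a list with fields
#'   `TP`, `TN`, `FP`, `FN`.
#' @return `list(sn, sp, acc, mcc)`.
#' @export
metrics_from_confusion <- function(cc) {
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  tot <- TP + TN + FP + FN
  if (tot == 0) stop("empty confusion matrix")
  safe <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  list(sn = safe(TP, TP + FN),
       sp = safe(TN, TN + FP),
       acc = (TP + TN) / tot,
       mcc = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den)
}

#' ROC-AUC by midranks
#'
#' Equals the probability that a random positive outscores a random
#' negative, ties counted half (the Mann-Whitney statistic).
#'
#' @inheritParams confusion_counts
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  np <- sum(labels == 1); nn <- sum(labels != 1)
  if (np == 0 || nn == 0)
    stop("roc_auc requires both classes to be present")
  r <- rank(scores)                       # midranks for ties
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Precision-recall AUC by the step-wise area
#'
#' Sweeps the decision threshold over the distinct scores (ties grouped),
#' accumulating `(recall_i - recall_{i-1}) * precision_i`.
#'
#' @inheritParams confusion_counts
#' @return PR-AUC in \[0, 1\].
#' @export
pr_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  np <- sum(labels == 1)
  if (np == 0) stop("pr_auc requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o] == 1
  sc <- scores[o]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)   # last index of each tie group
  tp <- tp[keep]; fp <- fp[keep]
  recall <- tp / np
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' F1 score from confusion counts
#'
#' `2*TP / (2*TP + FP + FN)`; 0 when the denominator is zero.
#'
#' @inheritParams metrics_from_confusion
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(cc) {
  den <- 2 * cc$TP + cc$FP + cc$FN
  if (den == 0) 0 else 2 * cc$TP / den
}

#' Full metrics report for a score vector
#'
#' Thresholds the scores, tallies the confusion matrix and reports Sn, Sp,
#' Acc, MCC, F1, ROC-AUC and PR-AUC.
#'
#' @inheritParams confusion_counts
#' @return `list(sn, sp, acc, mcc, auc, f1, pr_auc, threshold, counts)` of
#'   class `m5c_metrics`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  cc <- confusion_counts(labels, scores, threshold)
  m <- metrics_from_confusion(cc)
  structure(c(m, list(auc = roc_auc(labels, scores),
                      f1 = f1_score(cc),
                      pr_auc = pr_auc(labels, scores),
                      threshold = threshold, counts = cc)),
            class = "m5c_metrics")
}

#' @export
print.m5c_metrics <- function(x, ...) {
  cat(sprintf(
    "Sn %.4f  Sp %.4f  Acc %.4f  MCC %.4f  AUC %.4f  F1 %.4f  PR-AUC %.4f\n",
    x$sn, x$sp, x$acc, x$mcc, x$auc, x$f1, x$pr_auc))
  cat(sprintf("threshold %.3g; TP %d TN %d FP %d FN %d\n", x$threshold,
              x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN))
  invisible(x)
}
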