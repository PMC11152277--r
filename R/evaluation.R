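# Metric suite: confusion counts, the 20-threshold F1 sweep, tie-corrected
# ROC AUC, and step-integrated area under the precision-recall curve.

#' Confusion counts at a threshold
#'
#' A sample is predicted positive iff its score is greater than or equal to
#' the threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1).
#' @param threshold decision threshold.
#' @return list with integer fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(scores, labels, threshold) {
  fl_assert(length(scores) == length(labels),
            "scores and labels must have equal length")
  pred <- scores >= threshold
  pos <- labels == 1
  list(TP = sum(pred & pos), FP = sum(pred & !pos),
       TN = sum(!pred & !pos), FN = sum(!pred & pos))
}

f1_at <- function(scores, labels, threshold) {
  cm <- confusion(scores, labels, threshold)
  if (cm$TP + cm$FP == 0 || cm$TP + cm$FN == 0) return(0)
  prec <- cm$TP / (cm$TP + cm$FP)
  rec <- cm$TP / (cm$TP + cm$FN)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Best F1 over the 20-threshold sweep
#'
#' Evaluates the thresholds 0.00, 0.05, ..., 0.95 (20 values), computes the
#' F1 score at each (defined as 0 when precision or recall is undefined),
#' and returns the maximum together with the smallest threshold achieving
#' it.
#'
#' @inheritParams confusion
#' @return list with `best_f1` and `best_threshold`.
#' @export
f1_sweep <- function(scores, labels) {
  fl_assert(length(scores) > 0, "empty input")
  if (!any(labels == 1)) fl_stop("F1 undefined without positive labels")
  grid <- seq(0, 0.95, by = 0.05)
  f1s <- vapply(grid, function(t) f1_at(scores, labels, t), numeric(1))
  best <- which.max(f1s)                  # first (smallest) maximizer
  list(best_f1 = f1s[best], best_threshold = grid[best])
}

#' ROC AUC by the tie-corrected rank statistic
#'
#' Equals the probability that a uniformly chosen positive outranks a
#' uniformly chosen negative, counting ties as one half — the area under
#' the TPR-vs-FPR curve.
#'
#' @inheritParams confusion
#' @return scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) fl_stop("AUC requires both classes")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration over descending score thresholds: each increment of
#' recall contributes its precision (the average-precision form of AUPR).
#' With all scores identical this reduces to the positive prevalence.
#'
#' @inheritParams confusion
#' @return scalar in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  pos <- labels == 1
  if (!any(pos)) fl_stop("AUPR requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  y <- pos[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  # evaluate only at distinct-threshold boundaries (last index of each tie)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(pos)
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' All metrics for one score vector
#'
#' @inheritParams confusion
#' @return list with `precision`, `recall`, `f1`, `best_threshold`, `auc`,
#'   `aupr` (precision/recall reported at the best-F1 threshold).
#' @export
evaluate_scores <- function(scores, labels) {
  sw <- f1_sweep(scores, labels)
  cm <- confusion(scores, labels, sw$best_threshold)
  precision <- if (cm$TP + cm$FP > 0) cm$TP / (cm$TP + cm$FP) else 0
  recall <- if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else 0
  list(precision = precision, recall = recall, f1 = sw$best_f1,
       best_threshold = sw$best_threshold,
       auc = roc_auc(scores, labels), aupr = aupr(scores, labels))
}
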