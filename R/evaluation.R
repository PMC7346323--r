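#' Overlap score between two binary masks
#'
#' Intersection-over-union \eqn{S = |GT \cap SM| / |GT \cup SM|}, the overlap
#' index used to score disc and cup segmentations. Two empty masks are in
#' perfect agreement and score 1.
#'
#' @param gt,sm binary masks (0/1 matrices) on the same grid.
#' @return overlap score in `[0, 1]`.
#' @export
overlap_score <- function(gt, sm) {
  if (!identical(dim(gt), dim(sm))) stop_fs("mask grids differ")
  gt <- gt > 0; sm <- sm > 0
  uni <- sum(gt | sm)
  if (uni == 0) return(1)
  sum(gt & sm) / uni
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity, the mask-level accuracy used for
#' segmentation evaluation.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @return `(sensitivity + specificity) / 2`.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0 | c(sensitivity, specificity) > 1)) {
    stop_fs("sensitivity and specificity must be in [0, 1]")
  }
  (sensitivity + specificity) / 2
}

#' Absolute CDR error
#'
#' \eqn{\delta_{CDR} = |CDR_g - CDR_p|} between a ground-truth and a
#' predicted cup-to-disc ratio.
#'
#' @param cdr_g,cdr_p cup-to-disc ratios.
#' @return absolute difference.
#' @export
cdr_error <- function(cdr_g, cdr_p) abs(cdr_g - cdr_p)

#' Pixel-level sensitivity/specificity of a segmentation
#'
#' Helper combining a mask pair into the balanced accuracy of
#' [balanced_accuracy()]: sensitivity = TP rate over ground-truth-positive
#' pixels, specificity = TN rate over ground-truth-negative pixels.
#'
#' @param gt,sm binary masks on the same grid.
#' @return named vector `sensitivity`, `specificity`, `balanced_accuracy`.
#' @export
mask_accuracy <- function(gt, sm) {
  if (!identical(dim(gt), dim(sm))) stop_fs("mask grids differ")
  gt <- gt > 0; sm <- sm > 0
  sens <- if (sum(gt) == 0) 1 else sum(gt & sm) / sum(gt)
  spec <- if (sum(!gt) == 0) 1 else sum(!gt & !sm) / sum(!gt)
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = balanced_accuracy(sens, spec))
}

#' Classification metrics with ROC curve
#'
#' Confusion-matrix rates at a decision threshold, plus the full ROC curve
#' and its area computed by the trapezoidal rule. `accuracy` here is plain
#' proportion correct (the classification tables' ACC), distinct from the
#' mask-level [balanced_accuracy()].
#'
#' @param labels binary labels; 1/`TRUE`/`"glaucoma"` is the positive class.
#' @param scores numeric scores, larger = more positive.
#' @param threshold decision threshold; predicted positive iff
#'   `score >= threshold`.
#' @return list with `sensitivity`, `specificity`, `accuracy`, `auc`, and a
#'   data frame `roc` of (fpr, tpr) points.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop_fs("both classes must be present")
  pred <- scores >= threshold
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  tn <- sum(!pred & y == 0); fp <- sum(pred & y == 0)
  roc <- roc_points(y, scores)
  auc <- trapezoid_auc(roc$fpr, roc$tpr)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(y), auc = auc, roc = roc,
       threshold = threshold)
}

as_binary_label <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "glaucoma")
  } else {
    as.integer(labels > 0)
  }
}

# ROC curve over every distinct score threshold, from (0,0) to (1,1).
roc_points <- function(y, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  npos <- sum(y == 1); nneg <- sum(y == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  # collapse tied scores: keep the last index of each tie block
  s <- scores[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(fpr = c(0, fp[keep] / nneg), tpr = c(0, tp[keep] / npos))
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Contingency-table accuracy report
#'
#' Per-class and overall accuracy from raw counts of cases and correct
#' predictions, with the 4-decimal half-up display rounding used in
#' published screening tables.
#'
#' @param counts named integer vector of per-class case counts.
#' @param correct named integer vector of per-class correct predictions,
#'   same names as `counts`.
#' @return data frame with one row per class plus an `All` row; columns
#'   `class`, `count`, `correct`, `accuracy` (exact) and `accuracy_display`
#'   (rounded to 4 decimals, half up).
#' @export
contingency_report <- function(counts, correct) {
  if (!identical(names(counts), names(correct))) {
    stop_fs("counts and correct must share class names")
  }
  if (any(correct > counts)) stop_fs("correct predictions exceed counts")
  if (any(counts < 0) || any(correct < 0)) stop_fs("counts must be non-negative")
  cls <- names(counts)
  acc <- correct / counts
  total <- sum(counts); total_correct <- sum(correct)
  data.frame(
    class = c(cls, "All"),
    count = c(counts, total),
    correct = c(correct, total_correct),
    accuracy = c(acc, total_correct / total),
    accuracy_display = round_half_up(c(acc, total_correct / total), 4),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
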