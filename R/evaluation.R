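# Pixel-level evaluation against a ground-truth mask: confusion counts,
# sensitivity/specificity, and ROC/AUC by sweeping the score threshold
# from the most positive value downward.

#' Confusion counts between a predicted and a ground-truth mask
#'
#' @param mask,gt Binary matrices (`0/1` or logical) of equal shape; 1 =
#'   lesion.
#' @return List of class `confusion_counts` with integers `TP`, `FP`, `TN`,
#'   `FN` summing to the pixel count.
#' @export
confusion_counts <- function(mask, gt) {
  mask <- as.matrix(mask); gt <- as.matrix(gt)
  if (!all(dim(mask) == dim(gt)))
    stop("mask and ground truth must share a shape", call. = FALSE)
  if (!all(mask %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("masks must be binary", call. = FALSE)
  m <- mask == 1; g <- gt == 1
  structure(list(TP = sum(m & g), FP = sum(m & !g),
                 TN = sum(!m & !g), FN = sum(!m & g)),
            class = "confusion_counts")
}

#' Sensitivity and specificity
#'
#' `TP / (TP + FN)` and `TN / (FP + TN)`. An empty class yields `NA` for
#' the corresponding ratio instead of an error, so batch tables stay
#' rectangular.
#'
#' @param counts A [confusion_counts()] object (or list with `TP`, `FP`,
#'   `TN`, `FN`).
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
sensitivity_specificity <- function(counts) {
  sens <- if (counts$TP + counts$FN > 0)
    counts$TP / (counts$TP + counts$FN) else NA_real_
  spec <- if (counts$FP + counts$TN > 0)
    counts$TN / (counts$FP + counts$TN) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' ROC curve and AUC by threshold sweep
#'
#' Thresholds are the unique score values (or `n_thresholds` quantiles when
#' there are more unique values than that), swept from the most positive to
#' the most negative; at each threshold the predicted lesion is
#' `score >= t`. The `(0, 0)` and `(1, 1)` anchors are appended and the AUC
#' is the trapezoidal area, which on the full unique-value sweep equals the
#' Mann-Whitney statistic `P(score_lesion > score_skin) + P(tie) / 2`.
#'
#' @param score Numeric matrix of lesion scores.
#' @param gt Binary ground-truth mask of the same shape, with both classes
#'   present.
#' @param n_thresholds Cap on the number of thresholds (default unlimited).
#' @return Object of class `roc_curve`: list with `thresholds`
#'   (decreasing), `fpr`, `tpr` (anchored, same length as thresholds plus
#'   two) and `auc`.
#' @export
roc_curve <- function(score, gt, n_thresholds = Inf) {
  score <- as.matrix(score); gt <- as.matrix(gt)
  if (!all(dim(score) == dim(gt)))
    stop("score and ground truth must share a shape", call. = FALSE)
  g <- as.numeric(gt) == 1
  if (all(g) || !any(g))
    stop("ground truth must contain both classes", call. = FALSE)
  s <- as.numeric(score)
  thr <- sort(unique(s), decreasing = TRUE)
  if (is.finite(n_thresholds) && length(thr) > n_thresholds)
    thr <- sort(unique(stats::quantile(s, probs = seq(0, 1,
                                                      length.out = n_thresholds),
                                       names = FALSE, type = 7)),
                decreasing = TRUE)
  npos <- sum(g); nneg <- sum(!g)
  tpr <- vapply(thr, function(t) sum(s[g] >= t) / npos, numeric(1L))
  fpr <- vapply(thr, function(t) sum(s[!g] >= t) / nneg, numeric(1L))
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", length(x$thresholds), " threshold(s), AUC = ",
      format(x$auc, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Evaluate a batch of score maps against ground truths
#'
#' For each (score, ground truth) pair: sensitivity and specificity of the
#' thresholded mask at `threshold`, plus the threshold-sweep AUC.
#'
#' @param scores List of score matrices.
#' @param gts List of ground-truth masks, parallel to `scores`.
#' @param labels Optional character vector of row labels (e.g. method or
#'   image names).
#' @param threshold Mask threshold for the point estimates.
#' @return Data frame with columns `label`, `sensitivity`, `specificity`,
#'   `auc`.
#' @export
evaluate_batch <- function(scores, gts, labels = NULL, threshold = 0.5) {
  stopifnot(length(scores) >= 1L, length(scores) == length(gts))
  if (is.null(labels)) labels <- as.character(seq_along(scores))
  rows <- lapply(seq_along(scores), function(i) {
    ss <- sensitivity_specificity(
      confusion_counts((as.matrix(scores[[i]]) >= threshold) * 1, gts[[i]]))
    data.frame(label = labels[i],
               sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]],
               auc = roc_curve(scores[[i]], gts[[i]])$auc)
  })
  do.call(rbind, rows)
}
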