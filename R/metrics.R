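# Evaluation stack: argmax compression, one-vs-rest confusion counts,
# macro-averaged IoU / Dice / precision / recall, micro pixel accuracy, and
# tie-aware ROC/AUC for the mutation classifier.

#' Compress a probability map to a label mask
#'
#' Per-pixel argmax over the channel dimension; ties are broken toward the
#' lowest class index, so a uniform map compresses to class 0.
#'
#' @param S Probability map, `(H, W, C)` array.
#' @return A [label_mask()] with classes `0..C-1`.
#' @export
compress_to_labels <- function(S) {
  d <- dim(S)
  if (length(d) != 3L) stop("expected an (H, W, C) probability map")
  best <- matrix(0L, d[1L], d[2L])
  bestv <- S[, , 1L]
  for (ci in seq_len(d[3L])[-1L]) {
    upd <- S[, , ci] > bestv
    best[upd] <- ci - 1L
    bestv <- pmax(bestv, S[, , ci])
  }
  label_mask(best, n_classes = d[3L])
}

#' Per-class confusion counts between two label masks
#'
#' One-vs-rest pixel counts for each class: TP, FP, TN, FN, satisfying
#' `TP + FP + TN + FN = total pixels` for every class and
#' `sum(TP) = number of correctly labeled pixels`.
#'
#' @param pred,truth Label masks (or integer matrices) of identical shape.
#' @param n_classes Number of classes; defaults to what the masks declare.
#' @return A `tmeseg_confusion` list with vectors `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth, n_classes = NULL) {
  pm <- mask_labels(pred); tm <- mask_labels(truth)
  if (!identical(dim(pm), dim(tm))) stop("shape mismatch between pred and truth")
  if (is.null(n_classes))
    n_classes <- max(mask_classes(pred), mask_classes(truth),
                     max(pm) + 1L, max(tm) + 1L)
  C <- as.integer(n_classes)
  tot <- length(pm)
  # C x C contingency table: rows = truth, cols = pred
  M <- matrix(tabulate(as.integer(tm) + C * as.integer(pm) + 1L, nbins = C * C),
              nrow = C)
  tp <- diag(M)
  fp <- colSums(M) - tp          # predicted c, truth != c
  fn <- rowSums(M) - tp          # truth c, predicted != c
  tn <- tot - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n_classes = C, total = tot),
            class = "tmeseg_confusion")
}

# Classes counted in the macro average: present in prediction or truth.
# Absent-from-both classes (TP+FP+FN = 0) are excluded rather than scored,
# so a model is not rewarded for classes that never occur.
macro_average <- function(counts, per_class_fn) {
  keep <- (counts$tp + counts$fp + counts$fn) > 0
  if (!any(keep)) return(NA_real_)
  vals <- per_class_fn(counts)
  mean(vals[keep])
}

per_class_iou <- function(counts) {
  den <- counts$tp + counts$fp + counts$fn
  ifelse(den > 0, counts$tp / den, 0)
}

per_class_dice <- function(counts) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  ifelse(den > 0, 2 * counts$tp / den, 0)
}

#' Macro-averaged intersection-over-union
#'
#' Per-class `IoU_c = TP_c / (TP_c + FP_c + FN_c)`, averaged over the classes
#' present in prediction or truth. A class present in exactly one of the two
#' scores 0; a class absent from both is excluded from the average.
#'
#' @param counts A [confusion_counts()] result.
#' @return Fraction in `[0, 1]`.
#' @export
macro_iou <- function(counts) macro_average(counts, per_class_iou)

#' Macro-averaged Dice coefficient
#'
#' Per-class `Dice_c = 2 TP_c / (2 TP_c + FP_c + FN_c)`, macro-averaged with
#' the same empty-class rule as [macro_iou()]. Satisfies
#' `Dice_c = 2 IoU_c / (1 + IoU_c)` classwise, hence macro Dice >= macro IoU.
#'
#' @inheritParams macro_iou
#' @return Fraction in `[0, 1]`.
#' @export
macro_dice <- function(counts) macro_average(counts, per_class_dice)

#' Macro-averaged precision
#'
#' Per-class `TP_c / (TP_c + FP_c)` (0 when the class is never predicted but
#' occurs in truth), macro-averaged with the empty-class exclusion rule.
#'
#' @inheritParams macro_iou
#' @return Fraction in `[0, 1]`.
#' @export
macro_precision <- function(counts) {
  macro_average(counts, function(cc) {
    den <- cc$tp + cc$fp
    ifelse(den > 0, cc$tp / den, 0)
  })
}

#' Macro-averaged recall
#'
#' Per-class `TP_c / (TP_c + FN_c)` (0 when the class occurs only in the
#' prediction), macro-averaged with the empty-class exclusion rule.
#'
#' @inheritParams macro_iou
#' @return Fraction in `[0, 1]`.
#' @export
macro_recall <- function(counts) {
  macro_average(counts, function(cc) {
    den <- cc$tp + cc$fn
    ifelse(den > 0, cc$tp / den, 0)
  })
}

#' Overall pixel accuracy
#'
#' Fraction of pixels whose predicted class equals the truth (micro accuracy;
#' equals `sum(TP_c) / total` on the confusion counts).
#'
#' @inheritParams confusion_counts
#' @return Fraction in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  pm <- mask_labels(pred); tm <- mask_labels(truth)
  if (!identical(dim(pm), dim(tm))) stop("shape mismatch between pred and truth")
  mean(pm == tm)
}

#' Bundle the five segmentation metrics
#'
#' @inheritParams macro_iou
#' @param accuracy Micro pixel accuracy to include in the report.
#' @return A `tmeseg_metrics` list: accuracy, precision, recall, dice, iou.
#' @export
metrics_report <- function(counts, accuracy = sum(counts$tp) / counts$total) {
  structure(list(accuracy = accuracy,
                 precision = macro_precision(counts),
                 recall = macro_recall(counts),
                 dice = macro_dice(counts),
                 iou = macro_iou(counts)),
            class = "tmeseg_metrics")
}

#' @export
print.tmeseg_metrics <- function(x, ...) {
  cat(sprintf(
    "segmentation metrics: accuracy %.4f | precision %.4f | recall %.4f | dice %.4f | IoU %.4f\n",
    x$accuracy, x$precision, x$recall, x$dice, x$iou))
  invisible(x)
}

#' ROC curve and AUC by the rank statistic
#'
#' AUC is computed exactly as the tie-aware Mann-Whitney probability that a
#' random positive outranks a random negative (ties credited 0.5), which is
#' invariant under strictly monotone transforms of the scores. ROC points are
#' swept over the distinct score thresholds.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (0/1 or logical), same length.
#' @return List with `auc` and a `roc` data frame (threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: need at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  thr <- scores[ord]
  tp <- cumsum(labels[ord] == 1L)
  fp <- cumsum(labels[ord] == 0L)
  last <- !duplicated(thr, fromLast = TRUE)          # one point per threshold
  roc <- data.frame(threshold = c(Inf, thr[last]),
                    fpr = c(0, fp[last] / nneg),
                    tpr = c(0, tp[last] / npos))
  list(roc = roc, auc = auc)
}
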