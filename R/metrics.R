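# Detection evaluation (precision, recall, average precision over a
# score-sorted precision-recall sweep) and the positioning-error statistics
# used to assess 3D localization in the robot base frame.

#' Detection precision in percent
#'
#' `100 * TP / (TP + FP)`; defined as 0 when no predictions were kept
#' (zero-denominator convention).
#'
#' @param tp,fp True/false positive counts (non-negative).
#' @return Percentage in [0, 100].
#' @export
precision_pct <- function(tp, fp) {
  if (tp < 0 || fp < 0) stop("counts must be non-negative")
  if (tp + fp == 0) return(0)
  100 * tp / (tp + fp)
}

#' Detection recall in percent
#'
#' `100 * TP / (TP + FN)`; defined as 0 when there are neither true
#' positives nor false negatives.
#'
#' @param tp,fn True positive / false negative counts (non-negative).
#' @return Percentage in [0, 100].
#' @export
recall_pct <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop("counts must be non-negative")
  if (tp + fn == 0) return(0)
  100 * tp / (tp + fn)
}

# score-ordered TP/FP flags via greedy IoU matching (each ground-truth box
# matched at most once, per image)
match_predictions <- function(pred, gt, iou_thr) {
  ord <- order(-pred$score, seq_len(nrow(pred)))
  pred <- pred[ord, , drop = FALSE]
  tp <- logical(nrow(pred))
  used <- rep(FALSE, nrow(gt))
  for (i in seq_len(nrow(pred))) {
    gi <- which(gt$image == pred$image[i] & !used)
    if (length(gi) == 0L) next
    ious <- box_iou(as.matrix(pred[i, c("xmin", "ymin", "xmax", "ymax")]),
                    as.matrix(gt[gi, c("xmin", "ymin", "xmax", "ymax")]))
    j <- which.max(ious[1, ])
    if (ious[1, j] >= iou_thr) {
      tp[i] <- TRUE
      used[gi[j]] <- TRUE
    }
  }
  list(tp = tp, scores = pred$score)
}

#' Average precision of a single-class detector
#'
#' Sorts predictions by score, matches them greedily to ground truth at the
#' given IoU threshold (each ground-truth box used at most once), sweeps the
#' resulting precision-recall staircase and sums precision over recall
#' increments.  With one class the mean average precision equals this AP.
#'
#' @param pred Data frame with columns image, xmin, ymin, xmax, ymax, score.
#' @param gt Data frame with columns image, xmin, ymin, xmax, ymax.
#' @param iou_thr IoU threshold for a prediction to count as a hit
#'   (default 0.5).
#' @param method `"interp"` (all-point interpolated precision envelope, the
#'   default) or `"staircase"` (raw precision at each recall increment).
#' @return AP in percent.
#' @export
average_precision <- function(pred, gt, iou_thr = 0.5,
                              method = c("interp", "staircase")) {
  method <- match.arg(method)
  if (nrow(gt) == 0L) stop("average_precision: no ground-truth boxes")
  if (nrow(pred) == 0L) return(0)
  m <- match_predictions(pred, gt, iou_thr)
  tp <- cumsum(m$tp)
  fp <- cumsum(!m$tp)
  rec <- tp / nrow(gt)
  prec <- tp / (tp + fp)
  if (method == "interp") {
    # precision envelope: running max from the right
    penv <- rev(cummax(rev(prec)))
    dr <- diff(c(0, rec))
    return(100 * sum(penv * dr))
  }
  dr <- diff(c(0, rec))
  100 * sum(prec * dr)
}

#' Mean average precision over IoU thresholds
#'
#' @param pred,gt As in [average_precision()].
#' @param iou_thrs Vector of IoU thresholds; default the single conventional
#'   0.5; use `seq(0.5, 0.95, 0.05)` for the stricter averaged form.
#' @param method Passed to [average_precision()].
#' @return mAP in percent (mean of per-threshold APs).
#' @export
mean_average_precision <- function(pred, gt, iou_thrs = 0.5,
                                   method = "interp") {
  mean(vapply(iou_thrs, function(t)
    average_precision(pred, gt, t, method), numeric(1)))
}

#' Detection metrics at a fixed confidence threshold
#'
#' @param pred,gt As in [average_precision()]; `pred` is already
#'   score-filtered.
#' @param iou_thr IoU threshold for matching.
#' @return List of class `detection_metrics` with TP, FP, FN, precision,
#'   recall, mAP (all percentages in [0, 100]).
#' @export
detection_metrics <- function(pred, gt, iou_thr = 0.5) {
  m <- if (nrow(pred) > 0L) match_predictions(pred, gt, iou_thr)
       else list(tp = logical(0))
  tp <- sum(m$tp); fp <- sum(!m$tp); fn <- nrow(gt) - tp
  structure(list(TP = tp, FP = fp, FN = fn,
                 precision = precision_pct(tp, fp),
                 recall = recall_pct(tp, fn),
                 mAP = if (nrow(gt) > 0L)
                   average_precision(pred, gt, iou_thr) else NA_real_),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d  precision=%.2f%% recall=%.2f%% mAP=%.2f%%\n",
              x$TP, x$FP, x$FN, x$precision, x$recall, x$mAP))
  invisible(x)
}

#' Positioning-error statistics per axis
#'
#' For signed localization errors measured along the robot-base X, Y and Z
#' axes: the mean absolute error per axis and the standard error of the
#' measurements (sample standard deviation divided by the square root of the
#' number of measurement points).
#'
#' @param x,y,z Numeric vectors of signed per-measurement errors (same
#'   length), in the stated unit (typically mm).
#' @param unit Unit label carried through to the report.
#' @param se Whether to compute standard errors (requires n >= 2).
#' @return List of class `localization_error_report` with `delta` (mean
#'   absolute errors), `se` (standard errors), `n`, `unit`.
#' @export
localization_errors <- function(x, y, z, unit = "mm", se = TRUE) {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("error vectors must have equal length")
  if (n < 1L) stop("need at least one measurement point")
  if (se && n < 2L)
    stop("standard error requires at least 2 measurement points")
  delta <- c(X = mean(abs(x)), Y = mean(abs(y)), Z = mean(abs(z)))
  se <- if (se)
    c(X = stats::sd(x), Y = stats::sd(y), Z = stats::sd(z)) / sqrt(n)
  else c(X = NA_real_, Y = NA_real_, Z = NA_real_)
  structure(list(delta = delta, se = se, n = n, unit = unit,
                 errors = cbind(X = x, Y = y, Z = z)),
            class = "localization_error_report")
}

#' @export
print.localization_error_report <- function(x, ...) {
  cat(sprintf("n=%d measurement points (%s)\n", x$n, x$unit))
  cat(sprintf("  mean absolute error: X=%.2f Y=%.2f Z=%.2f\n",
              x$delta["X"], x$delta["Y"], x$delta["Z"]))
  if (!is.na(x$se["X"]))
    cat(sprintf("  standard error:      X=%.2f Y=%.2f Z=%.2f\n",
                x$se["X"], x$se["Y"], x$se["Z"]))
  invisible(x)
}
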