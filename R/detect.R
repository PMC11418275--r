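# Inference-side geometry: distribution-to-box decoding of the anchor-free
# head outputs, greedy non-maximum suppression, and the picking-point
# arithmetic on detection boxes.

#' Centre of a detection box
#'
#' Arithmetic midpoint `((xmin+xmax)/2, (ymin+ymax)/2)` of a box, the 2D
#' picking point of a detected fruit.  Real-valued; no rounding is applied
#' until a pixel lookup is needed.
#'
#' @param b Numeric vector `c(xmin, ymin, xmax, ymax)` or a data frame with
#'   those columns.
#' @return Numeric vector `c(x, y)` or a two-column matrix.
#' @export
box_center <- function(b) {
  if (is.data.frame(b))
    return(cbind(x = (b$xmin + b$xmax) / 2, y = (b$ymin + b$ymax) / 2))
  c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)
}

#' Pairwise intersection-over-union of axis-aligned boxes
#'
#' @param a,b Matrices with columns xmin, ymin, xmax, ymax.
#' @return `nrow(a) x nrow(b)` IoU matrix.
#' @export
box_iou <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 4)
  b <- matrix(as.numeric(b), ncol = 4)
  n <- nrow(a); m <- nrow(b)
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  area_a <- pmax(0, a[, 3] - a[, 1]) * pmax(0, a[, 4] - a[, 2])
  area_b <- pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
  un <- outer(area_a, area_b, "+") - inter
  iou <- inter / un
  iou[un <= 0] <- 0
  matrix(iou, n, m)
}

#' Greedy non-maximum suppression
#'
#' Keeps the highest-scoring box and discards boxes overlapping it above the
#' IoU threshold, repeatedly.  Ties are broken deterministically by score,
#' then box area, then input index, so the result does not depend on input
#' ordering.
#'
#' @param boxes Data frame with columns xmin, ymin, xmax, ymax, score.
#' @param iou_thr IoU threshold above which the lower-scoring box is dropped.
#' @return The surviving rows of `boxes` in decreasing score order.
#' @export
nms <- function(boxes, iou_thr = 0.45) {
  if (nrow(boxes) == 0L) return(boxes)
  area <- (boxes$xmax - boxes$xmin) * (boxes$ymax - boxes$ymin)
  ord <- order(-boxes$score, -area, seq_len(nrow(boxes)))
  b <- boxes[ord, , drop = FALSE]
  bm <- as.matrix(b[, c("xmin", "ymin", "xmax", "ymax")])
  keep <- logical(nrow(b))
  alive <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(b)) {
      j <- (i + 1L):nrow(b)
      ious <- box_iou(bm[i, , drop = FALSE], bm[j, , drop = FALSE])
      alive[j][ious[1, ] > iou_thr] <- FALSE
    }
  }
  b[keep, , drop = FALSE]
}

#' Decode raw head outputs into detection boxes
#'
#' Per-cell distribution-to-box decoding at strides 8/16/32: the four side
#' distances are expectations over softmax bin distributions scaled by the
#' stride, class scores pass through a sigmoid, low-confidence cells are
#' dropped and greedy NMS resolves duplicates.  Boxes are clipped to the
#' image bounds.
#'
#' @param outs List of per-scale head output arrays from [forward_model()].
#' @param model The `jd_model` that produced them (for strides/nc/reg_max).
#' @param conf Confidence threshold (default 0.25).
#' @param iou IoU threshold for NMS (default 0.45).
#' @param img_w,img_h Image bounds for clipping; inferred from the stride-8
#'   map when missing.
#' @return Data frame with columns xmin, ymin, xmax, ymax, score, class.
#' @export
decode_and_nms <- function(outs, model, conf = 0.25, iou = 0.45,
                           img_w = NULL, img_h = NULL) {
  dm <- model$rows[[model$det]]$mod
  reg_max <- dm$reg_max; nc <- dm$nc
  strides <- model$strides
  if (is.null(img_w)) img_w <- dim(outs[[1]])[2] * strides[1]
  if (is.null(img_h)) img_h <- dim(outs[[1]])[1] * strides[1]
  rows <- list()
  for (s in seq_along(outs)) {
    o <- outs[[s]]; st <- strides[s]
    H <- dim(o)[1]; W <- dim(o)[2]
    ncell <- H * W
    box <- matrix(o[, , 1:(4L * reg_max)], nrow = ncell)
    cls <- matrix(o[, , (4L * reg_max + 1L):(4L * reg_max + nc)],
                  nrow = ncell)
    score <- sigmoid(cls)
    best_cls <- max.col(score, ties.method = "first")
    best_score <- score[cbind(seq_len(ncell), best_cls)]
    keep <- which(best_score >= conf)
    if (length(keep) == 0L) next
    # expectation over softmax bins, one distribution per side
    dist <- matrix(0, length(keep), 4L)
    bins <- seq(0, reg_max - 1L)
    for (side in 1:4) {
      logits <- box[keep, ((side - 1L) * reg_max + 1L):(side * reg_max),
                    drop = FALSE]
      p <- softmax_rows(logits)
      dist[, side] <- p %*% bins
    }
    ci <- (keep - 1L) %% H + 1L      # row (y) index, column-major layout
    cj <- (keep - 1L) %/% H + 1L     # col (x) index
    xc <- (cj - 0.5) * st
    yc <- (ci - 0.5) * st
    rows[[length(rows) + 1L]] <- data.frame(
      xmin = pmax(0, xc - dist[, 1] * st),
      ymin = pmax(0, yc - dist[, 2] * st),
      xmax = pmin(img_w, xc + dist[, 3] * st),
      ymax = pmin(img_h, yc + dist[, 4] * st),
      score = best_score[keep],
      class = best_cls[keep] - 1L)
  }
  if (length(rows) == 0L)
    return(data.frame(xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0),
                      score = numeric(0), class = integer(0)))
  all <- do.call(rbind, rows)
  out <- nms(all, iou)
  rownames(out) <- NULL
  out
}

#' Run detection on an image
#'
#' Letterboxes the image to the model's input size, runs a forward pass,
#' decodes and suppresses, and maps boxes back to original image
#' coordinates.
#'
#' @param model A `jd_model`.
#' @param image `H x W x 3` array in [0, 1].
#' @param conf,iou Thresholds passed to [decode_and_nms()].
#' @param imgsz Network input size (defaults to the model config's).
#' @return Data frame of detections in original image pixel coordinates.
#' @export
detect_image <- function(model, image, conf = 0.25, iou = 0.45,
                         imgsz = NULL) {
  if (is.null(imgsz)) imgsz <- model$cfg$imgsz
  lb <- letterbox(image, imgsz)
  outs <- forward_model(model, lb$image)
  det <- decode_and_nms(outs, model, conf, iou, imgsz, imgsz)
  unletterbox_boxes(det, lb)
}

#' Letterbox an image to a square size
#'
#' Aspect-preserving nearest-neighbour resize followed by symmetric padding.
#' The returned parameters invert the mapping for boxes.
#'
#' @param image `H x W x C` array.
#' @param size Target square side in pixels.
#' @return List with `image`, `scale`, `pad_x`, `pad_y`, `orig_w`, `orig_h`.
#' @export
letterbox <- function(image, size) {
  d <- fm_dims(image)
  sc <- min(size / d[1], size / d[2])
  nh <- max(1L, round(d[1] * sc)); nw <- max(1L, round(d[2] * sc))
  res <- resize_nearest(image, nh, nw)
  py <- (size - nh) %/% 2L; px <- (size - nw) %/% 2L
  out <- array(0.5, c(size, size, d[3]))
  out[(py + 1L):(py + nh), (px + 1L):(px + nw), ] <- res
  list(image = out, scale = sc, pad_x = px, pad_y = py,
       orig_w = d[2], orig_h = d[1])
}

#' @rdname letterbox
#' @param boxes Data frame of boxes in letterboxed coordinates.
#' @param lb The parameter list returned by [letterbox()].
#' @export
unletterbox_boxes <- function(boxes, lb) {
  if (nrow(boxes) == 0L) return(boxes)
  boxes$xmin <- pmax(0, pmin(lb$orig_w, (boxes$xmin - lb$pad_x) / lb$scale))
  boxes$xmax <- pmax(0, pmin(lb$orig_w, (boxes$xmax - lb$pad_x) / lb$scale))
  boxes$ymin <- pmax(0, pmin(lb$orig_h, (boxes$ymin - lb$pad_y) / lb$scale))
  boxes$ymax <- pmax(0, pmin(lb$orig_h, (boxes$ymax - lb$pad_y) / lb$scale))
  boxes
}

# nearest-neighbour resize of an H x W x C array
resize_nearest <- function(image, nh, nw) {
  d <- fm_dims(image)
  ri <- pmin(d[1], pmax(1L, ceiling(seq_len(nh) * d[1] / nh)))
  ci <- pmin(d[2], pmax(1L, ceiling(seq_len(nw) * d[2] / nw)))
  image[ri, ci, , drop = FALSE]
}
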