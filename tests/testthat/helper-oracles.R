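# Independent oracles used by the test suite.  These deliberately share no
# code with the package implementation: plain-loop convolution, and a
# threshold-sweep precision-recall integration for average precision.

# brute-force 2D convolution (stride 1, zero padding), plain loops
brute_conv3x3 <- function(x, w, pad = 1L) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; cin <- d[3]; cout <- dim(w)[4]
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  y <- array(0, c(H, W, cout))
  for (oc in seq_len(cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (ic in seq_len(cin)) for (ki in 1:3) for (kj in 1:3) {
      acc <- acc + xp[i + ki - 1, j + kj - 1, ic] * w[ki, kj, ic, oc]
    }
    y[i, j, oc] <- acc
  }
  y
}

# inference-mode batch norm with fresh statistics (running mean 0, var 1)
brute_bn_fresh <- function(y, gamma, beta, eps = 1e-5) {
  for (c in seq_len(dim(y)[3]))
    y[, , c] <- gamma[c] * y[, , c] / sqrt(1 + eps) + beta[c]
  y
}

brute_silu <- function(x) x / (1 + exp(-x))

# independent AP: greedy matching re-implemented with explicit loops, then
# rectangular integration of the raw precision-recall staircase
brute_force_ap <- function(pred, gt, iou_thr = 0.5) {
  iou1 <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
    if (ua <= 0) 0 else inter / ua
  }
  ord <- order(-pred$score)
  matched <- rep(FALSE, nrow(gt))
  flags <- logical(nrow(pred))
  for (r in seq_along(ord)) {
    i <- ord[r]
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gt))) {
      if (matched[j] || gt$image[j] != pred$image[i]) next
      v <- iou1(as.numeric(pred[i, c("xmin", "ymin", "xmax", "ymax")]),
                as.numeric(gt[j, c("xmin", "ymin", "xmax", "ymax")]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= iou_thr) { flags[r] <- TRUE; matched[bj] <- TRUE }
  }
  ap <- 0; tp <- 0; prev_rec <- 0
  for (r in seq_along(flags)) {
    if (flags[r]) {
      tp <- tp + 1
      rec <- tp / nrow(gt)
      prec <- tp / r
      ap <- ap + prec * (rec - prev_rec)
      prev_rec <- rec
    }
  }
  100 * ap
}

# random detection problem on one or more images
random_detection_case <- function(n_gt, n_pred, n_img = 1L) {
  gt <- data.frame(image = sample.int(n_img, n_gt, replace = TRUE),
                   xmin = runif(n_gt, 0, 60), ymin = runif(n_gt, 0, 60))
  gt$xmax <- gt$xmin + runif(n_gt, 8, 30)
  gt$ymax <- gt$ymin + runif(n_gt, 8, 30)
  base <- gt[sample.int(n_gt, n_pred, replace = TRUE), ]
  pred <- data.frame(image = base$image,
                     xmin = base$xmin + rnorm(n_pred, 0, 6),
                     ymin = base$ymin + rnorm(n_pred, 0, 6))
  pred$xmax <- pred$xmin + (base$xmax - base$xmin) * runif(n_pred, 0.7, 1.3)
  pred$ymax <- pred$ymin + (base$ymax - base$ymin) * runif(n_pred, 0.7, 1.3)
  pred$score <- runif(n_pred)
  list(pred = pred, gt = gt)
}

# small occlusion-free training scenes shared by the trainer tests
tiny_scenes <- function(n, size = 64L, seed0 = 0L) {
  lapply(seq_len(n), function(i)
    generate_scene(scene_spec(width = size, height = size,
                              n_fruit = c(2L, 3L), radius = c(6, 12),
                              n_leaves = c(0L, 0L), seed = seed0 + i)))
}
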