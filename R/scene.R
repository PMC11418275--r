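# Synthetic orchard scenes: cluttered images of many small quasi-elliptical
# fruit among leaf-like occluders under varying illumination, with exact
# ground-truth boxes in both pixel and YOLO-normalised form.  Scenes are
# fully determined by their seed, so fixtures are generated in code rather
# than shipped.

#' Scene specification
#'
#' Parameters of one synthetic orchard image.  Defaults emulate the native
#' capture conditions of the emulated dataset: 640 x 480 images, many small
#' fruit (radii small relative to the frame), partial leaf occlusion and
#' global brightness variation.
#'
#' @param width,height Image size in pixels.
#' @param n_fruit Range (length-2) of fruit counts per scene.
#' @param radius Range of fruit semi-major axes in pixels.
#' @param n_leaves Range of leaf-shaped occluders.
#' @param leaf_opacity Opacity of occluders in [0, 1]; 1 hides fruit fully.
#' @param illumination Range of global brightness scaling factors.
#' @param visibility_threshold Minimum visible-area fraction for an occluded
#'   fruit to be annotated (default 0.25).
#' @param seed RNG seed; the seed fully determines the scene.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(width = 640L, height = 480L, n_fruit = c(6L, 18L),
                       radius = c(8, 22), n_leaves = c(6L, 16L),
                       leaf_opacity = 0.9, illumination = c(0.7, 1.3),
                       visibility_threshold = 0.25, seed = 0L) {
  stopifnot(width >= 32, height >= 32, n_fruit[1] <= n_fruit[2],
            radius[1] <= radius[2], n_leaves[1] <= n_leaves[2],
            leaf_opacity >= 0, leaf_opacity <= 1,
            illumination[1] <= illumination[2],
            visibility_threshold >= 0, visibility_threshold <= 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_fruit = as.integer(n_fruit), radius = radius,
                 n_leaves = as.integer(n_leaves),
                 leaf_opacity = leaf_opacity, illumination = illumination,
                 visibility_threshold = visibility_threshold,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# smooth 2D value-noise background
smooth_noise <- function(H, W, cells = 8L) {
  coarse <- matrix(stats::runif(cells * cells), cells, cells)
  ri <- pmin(cells, pmax(1, ceiling(seq_len(H) * cells / H)))
  ci <- pmin(cells, pmax(1, ceiling(seq_len(W) * cells / W)))
  coarse[ri, ci]
}

ellipse_mask <- function(H, W, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(W), each = H), H, W) - cx
  ys <- matrix(rep(seq_len(H), times = W), H, W) - cy
  xr <- xs * cos(theta) + ys * sin(theta)
  yr <- -xs * sin(theta) + ys * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate one synthetic orchard scene
#'
#' Renders a textured foliage background, shaded quasi-elliptical fruit and
#' semi-opaque leaf occluders, and returns the image together with
#' ground-truth annotations.  Fruit whose visible area (not covered by a
#' leaf or a nearer fruit) falls below the spec's visibility threshold are
#' excluded from the annotation list.  The same spec (same seed) always
#' produces the identical image and annotations.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (H x W x 3 array in [0, 1]), `annotations`
#'   (data frame: image, xmin, ymin, xmax, ymax, visibility), and `yolo`
#'   (character vector of normalised YOLO label lines).
#' @export
generate_scene <- function(spec) {
  with_rng(spec$seed, {
    H <- spec$height; W <- spec$width
    bg_g <- 0.25 + 0.35 * smooth_noise(H, W, 10L)
    bg_r <- 0.10 + 0.25 * smooth_noise(H, W, 7L)
    bg_b <- 0.05 + 0.15 * smooth_noise(H, W, 12L)
    img <- array(c(bg_r, bg_g, bg_b), c(H, W, 3L))

    nf <- if (spec$n_fruit[2] > spec$n_fruit[1])
      sample(spec$n_fruit[1]:spec$n_fruit[2], 1L) else spec$n_fruit[1]
    fruit <- list()
    owner <- matrix(0L, H, W)      # topmost fruit at each pixel
    if (nf > 0) for (i in seq_len(nf)) {
      a <- stats::runif(1, spec$radius[1], spec$radius[2])
      b <- a * stats::runif(1, 0.8, 1.05)       # slightly elongated
      cx <- stats::runif(1, a + 1, W - a - 1)
      cy <- stats::runif(1, b + 1, H - b - 1)
      th <- stats::runif(1, 0, pi)
      m <- ellipse_mask(H, W, cx, cy, a, b, th)
      # shaded jujube colours: red-brown with a highlight
      shade <- 0.65 + 0.35 * smooth_noise(H, W, 16L)
      col <- c(stats::runif(1, 0.55, 0.8), stats::runif(1, 0.25, 0.45),
               stats::runif(1, 0.1, 0.2))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- col[ch] * shade[m]
        img[, , ch] <- plane
      }
      owner[m] <- i
      fruit[[i]] <- list(cx = cx, cy = cy, a = a, b = b, theta = th,
                         area = sum(m), mask = m)
    }

    nl <- if (spec$n_leaves[2] > spec$n_leaves[1])
      sample(spec$n_leaves[1]:spec$n_leaves[2], 1L) else spec$n_leaves[1]
    covered <- matrix(FALSE, H, W)
    if (nl > 0) for (i in seq_len(nl)) {
      a <- stats::runif(1, 10, 40)
      b <- a * stats::runif(1, 0.25, 0.5)       # elongated leaf shape
      cx <- stats::runif(1, 1, W); cy <- stats::runif(1, 1, H)
      th <- stats::runif(1, 0, pi)
      m <- ellipse_mask(H, W, cx, cy, a, b, th)
      leaf_col <- c(stats::runif(1, 0.1, 0.25), stats::runif(1, 0.4, 0.65),
                    stats::runif(1, 0.1, 0.2))
      op <- spec$leaf_opacity
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- (1 - op) * plane[m] + op * leaf_col[ch]
        img[, , ch] <- plane
      }
      if (op > 0.5) covered[m] <- TRUE
    }

    illum <- stats::runif(1, spec$illumination[1], spec$illumination[2])
    img <- clamp01(img * illum)

    ann <- data.frame(image = integer(0), xmin = numeric(0),
                      ymin = numeric(0), xmax = numeric(0),
                      ymax = numeric(0), visibility = numeric(0))
    for (i in seq_along(fruit)) {
      f <- fruit[[i]]
      vis_px <- sum(owner == i & !covered)
      vis <- vis_px / f$area
      if (vis < spec$visibility_threshold) next
      hx <- sqrt((f$a * cos(f$theta))^2 + (f$b * sin(f$theta))^2)
      hy <- sqrt((f$a * sin(f$theta))^2 + (f$b * cos(f$theta))^2)
      ann <- rbind(ann, data.frame(
        image = spec$seed,
        xmin = max(0, f$cx - hx), ymin = max(0, f$cy - hy),
        xmax = min(W, f$cx + hx), ymax = min(H, f$cy + hy),
        visibility = vis))
    }
    list(image = img, annotations = ann,
         yolo = boxes_to_yolo(ann, W, H))
  })
}

#' Convert pixel boxes to YOLO label lines and back
#'
#' YOLO text format: one `class x_center y_center width height` row per
#' object, all coordinates normalised to [0, 1].  The two forms round-trip
#' to sub-pixel accuracy.
#'
#' @param ann Data frame with xmin, ymin, xmax, ymax in pixels.
#' @param W,H Image size in pixels.
#' @param class_id Class index written in the first column.
#' @return Character vector of label lines.
#' @export
boxes_to_yolo <- function(ann, W, H, class_id = 0L) {
  if (nrow(ann) == 0L) return(character(0))
  sprintf("%d %.6f %.6f %.6f %.6f", class_id,
          (ann$xmin + ann$xmax) / 2 / W, (ann$ymin + ann$ymax) / 2 / H,
          (ann$xmax - ann$xmin) / W, (ann$ymax - ann$ymin) / H)
}

#' @rdname boxes_to_yolo
#' @param lines Character vector of YOLO label lines.
#' @export
yolo_to_boxes <- function(lines, W, H) {
  if (length(lines) == 0L)
    return(data.frame(class = integer(0), xmin = numeric(0),
                      ymin = numeric(0), xmax = numeric(0),
                      ymax = numeric(0)))
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  data.frame(class = as.integer(m[, 1]),
             xmin = (m[, 2] - m[, 4] / 2) * W,
             ymin = (m[, 3] - m[, 5] / 2) * H,
             xmax = (m[, 2] + m[, 4] / 2) * W,
             ymax = (m[, 3] + m[, 5] / 2) * H)
}

#' Augment an image and its annotations
#'
#' Geometric operations transform boxes consistently; brightness leaves them
#' untouched.  Boxes pushed fully outside the frame are dropped; partially
#' outside boxes are clipped.
#'
#' @param image `H x W x 3` array.
#' @param ann Annotation data frame (xmin, ymin, xmax, ymax).
#' @param op One of `"brightness"`, `"translation"`, `"mirror"`,
#'   `"rotation"`.
#' @param params Operation parameters: `factor` (brightness), `dx`/`dy`
#'   pixels (translation), `angle` degrees (rotation); mirror takes none.
#' @return List with transformed `image` and `ann`.
#' @export
augment <- function(image, ann, op = c("brightness", "translation", "mirror",
                                       "rotation"), params = list()) {
  op <- match.arg(op)
  d <- fm_dims(image)
  H <- d[1]; W <- d[2]
  if (op == "brightness") {
    f <- params$factor %||% 1.2
    return(list(image = clamp01(image * f), ann = ann))
  }
  if (op == "mirror") {
    img <- image[, rev(seq_len(W)), , drop = FALSE]
    if (nrow(ann) > 0L) {
      x1 <- W - ann$xmax; x2 <- W - ann$xmin
      ann$xmin <- x1; ann$xmax <- x2
    }
    return(list(image = img, ann = ann))
  }
  if (op == "translation") {
    dx <- round(params$dx %||% 0); dy <- round(params$dy %||% 0)
    img <- array(0, dim(image))
    src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
    ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
    img[which(ok_r), which(ok_c), ] <-
      image[src_r[ok_r], src_c[ok_c], , drop = FALSE]
    if (nrow(ann) > 0L) {
      ann$xmin <- ann$xmin + dx; ann$xmax <- ann$xmax + dx
      ann$ymin <- ann$ymin + dy; ann$ymax <- ann$ymax + dy
      ann <- clip_boxes(ann, W, H)
    }
    return(list(image = img, ann = ann))
  }
  # rotation about the image centre; boxes become the axis-aligned hull of
  # their rotated corners, clipped to the frame
  th <- (params$angle %||% 10) * pi / 180
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xs <- matrix(rep(seq_len(W), each = H), H, W) - cx
  ys <- matrix(rep(seq_len(H), times = W), H, W) - cy
  sx <- xs * cos(-th) - ys * sin(-th) + cx   # inverse map
  sy <- xs * sin(-th) + ys * cos(-th) + cy
  si <- round(sy); sj <- round(sx)
  ok <- si >= 1 & si <= H & sj >= 1 & sj <= W
  img <- array(0, dim(image))
  lin <- cbind(si[ok], sj[ok])
  for (ch in 1:3) {
    plane_src <- image[, , ch]
    plane <- matrix(0, H, W)
    plane[ok] <- plane_src[lin]
    img[, , ch] <- plane
  }
  if (nrow(ann) > 0L) {
    rot <- function(x, y) {
      xr <- (x - cx) * cos(th) - (y - cy) * sin(th) + cx
      yr <- (x - cx) * sin(th) + (y - cy) * cos(th) + cy
      cbind(xr, yr)
    }
    newb <- t(vapply(seq_len(nrow(ann)), function(i) {
      p <- rbind(rot(ann$xmin[i], ann$ymin[i]), rot(ann$xmax[i], ann$ymin[i]),
                 rot(ann$xmin[i], ann$ymax[i]), rot(ann$xmax[i], ann$ymax[i]))
      c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
    }, numeric(4)))
    ann$xmin <- newb[, 1]; ann$ymin <- newb[, 2]
    ann$xmax <- newb[, 3]; ann$ymax <- newb[, 4]
    ann <- clip_boxes(ann, W, H)
  }
  list(image = img, ann = ann)
}

clip_boxes <- function(ann, W, H) {
  ann$xmin <- pmax(0, pmin(W, ann$xmin))
  ann$xmax <- pmax(0, pmin(W, ann$xmax))
  ann$ymin <- pmax(0, pmin(H, ann$ymin))
  ann$ymax <- pmax(0, pmin(H, ann$ymax))
  keep <- (ann$xmax - ann$xmin) > 1 & (ann$ymax - ann$ymin) > 1
  ann[keep, , drop = FALSE]
}

#' Split a dataset and expand it by augmentation
#'
#' Randomly partitions `n_images` indices by the given ratio using
#' largest-remainder rounding, then expands every split to
#' `(1 + augmentations_per_image)` times its size by adding augmented
#' copies.  Augmented copies always inherit the split of their source image,
#' so no content leaks across splits.  By default augmentation is applied to
#' all three splits, reproducing the arithmetic 930 -> 744/93/93 ->
#' 2232/279/279; set `augment_val_test = FALSE` for the methodologically
#' safer train-only expansion.
#'
#' @param n_images Number of source images.
#' @param ratio Length-3 split ratio summing to 1 (default 8:1:1).
#' @param augmentations_per_image Augmented copies added per image
#'   (default 2, i.e. tripling).
#' @param seed RNG seed for the random partition.
#' @param augment_val_test Whether validation/test splits are also expanded.
#' @return List with `train`, `val`, `test` (integer index vectors into the
#'   source images), `expanded` (data frame: split, source index, copy id),
#'   and `counts` (named before/after sizes).
#' @export
split_and_triple <- function(n_images, ratio = c(0.8, 0.1, 0.1),
                             augmentations_per_image = 2L, seed = 0L,
                             augment_val_test = TRUE) {
  if (abs(sum(ratio) - 1) > 1e-9) stop("ratio must sum to 1")
  if (n_images < 1L) stop("need at least one image")
  # largest-remainder assignment of split sizes
  raw <- n_images * ratio
  sizes <- floor(raw)
  rem <- n_images - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  perm <- with_rng(seed, sample.int(n_images))
  train <- sort(perm[seq_len(sizes[1])])
  val <- sort(perm[sizes[1] + seq_len(sizes[2])])
  test <- sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  expand <- function(idx, split) {
    k <- if (split == "train" || augment_val_test)
      augmentations_per_image else 0L
    data.frame(split = rep(split, length(idx) * (1L + k)),
               source = rep(idx, each = 1L + k),
               copy = rep(0:k, times = length(idx)))
  }
  expanded <- rbind(expand(train, "train"), expand(val, "val"),
                    expand(test, "test"))
  counts <- c(train = sum(expanded$split == "train"),
              val = sum(expanded$split == "val"),
              test = sum(expanded$split == "test"))
  list(train = train, val = val, test = test, expanded = expanded,
       counts = counts,
       before = c(train = length(train), val = length(val),
                  test = length(test)))
}

#' Generate a synthetic dataset on disk
#'
#' Writes PNG images, YOLO label files and a manifest YAML describing the
#' split, fully reproducible from the seed.
#'
#' @param n Number of scenes.
#' @param dir Output directory (created if needed).
#' @param seed Base RNG seed; scene i uses `seed + i`.
#' @param spec_args Named list of overrides passed to [scene_spec()].
#' @param ratio,augmentations_per_image Passed to [split_and_triple()].
#' @return The manifest list (invisibly written to `manifest.yaml`).
#' @export
simulate_dataset <- function(n, dir, seed = 0L, spec_args = list(),
                             ratio = c(0.8, 0.1, 0.1),
                             augmentations_per_image = 2L) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    spec <- do.call(scene_spec, c(spec_args, list(seed = seed + i)))
    sc <- generate_scene(spec)
    png::writePNG(sc$image, file.path(dir, "images", sprintf("img%04d.png", i)))
    writeLines(sc$yolo, file.path(dir, "labels", sprintf("img%04d.txt", i)))
  }
  sp <- split_and_triple(n, ratio, augmentations_per_image, seed)
  manifest <- list(n_images = n, seed = seed,
                   counts = as.list(sp$counts),
                   train = sp$train, val = sp$val, test = sp$test,
                   images = "images", labels = "labels")
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
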