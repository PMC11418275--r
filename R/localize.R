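# RGB-D 3D localization: pinhole deprojection of a detected fruit centre
# plus depth into the camera frame, and the rigid hand-eye transform
# (quaternion + translation, eye-to-hand) into the robot base frame.

#' Pinhole camera intrinsics
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels.
#' @return List of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy),
            class = "camera_intrinsics")
}

#' Hand-eye calibration record
#'
#' The rigid transform from the (stationary) camera frame to the robot base
#' frame, as estimated by an eye-to-hand calibration: a unit quaternion in
#' w-first order plus a translation of the camera origin expressed in the
#' base frame.
#'
#' @param q Quaternion `c(qw, qx, qy, qz)`; normalised on input.
#' @param t Translation `c(tx, ty, tz)`.
#' @param unit Length unit of `t` (`"m"` or `"mm"`); mandatory tag.
#' @return List of class `hand_eye_calibration`.
#' @export
hand_eye_calibration <- function(q, t, unit = c("m", "mm")) {
  unit <- match.arg(unit)
  nq <- sqrt(sum(q^2))
  if (nq < 1e-12) stop("quaternion norm too small")
  structure(list(q = q / nq, t = as.numeric(t), unit = unit),
            class = "hand_eye_calibration")
}

#' Tagged 3D point
#'
#' @param x,y,z Coordinates.
#' @param frame Frame tag, `"camera"` or `"base"`.
#' @param unit Length unit.
#' @return List of class `point3d`; `homogeneous()` gives `c(x, y, z, 1)`.
#' @export
point3d <- function(x, y, z, frame = c("camera", "base"), unit = "m") {
  frame <- match.arg(frame)
  structure(list(x = x, y = y, z = z, frame = frame, unit = unit),
            class = "point3d")
}

#' @rdname point3d
#' @param p A `point3d`.
#' @export
homogeneous <- function(p) c(p$x, p$y, p$z, 1)

#' @export
print.point3d <- function(p, ...) {
  cat(sprintf("(%.4f, %.4f, %.4f) [%s frame, %s]\n", p$x, p$y, p$z,
              p$frame, p$unit))
  invisible(p)
}

#' Deproject a pixel plus depth into the camera frame
#'
#' Pinhole model: `x = (u - cx) * depth / fx`, `y = (v - cy) * depth / fy`,
#' `z = depth`.
#'
#' @param u,v Pixel coordinates (x right, y down).
#' @param depth Depth reading at that pixel (> 0), in `unit`.
#' @param K A [camera_intrinsics()].
#' @param unit Length unit of `depth`.
#' @return A [point3d()] in the camera frame.
#' @export
deproject <- function(u, v, depth, K, unit = "m") {
  if (!is.finite(depth) || depth <= 0)
    stop("deproject: depth must be positive and finite")
  point3d((u - K$cx) * depth / K$fx, (v - K$cy) * depth / K$fy, depth,
          frame = "camera", unit = unit)
}

#' Rotation matrix of a unit quaternion
#'
#' Converts a w-first quaternion `(qw, qx, qy, qz)` into the corresponding
#' 3x3 rotation matrix (orthonormal, determinant +1).  The quaternion is
#' normalised first; `q` and `-q` give the same rotation.
#'
#' @param q Numeric vector `c(qw, qx, qy, qz)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_rotation <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("quaternion norm too small")
  q <- q / n
  qw <- q[1]; qx <- q[2]; qy <- q[3]; qz <- q[4]
  matrix(c(
    1 - 2 * qy^2 - 2 * qz^2, 2 * qx * qy - 2 * qz * qw, 2 * qx * qz + 2 * qy * qw,
    2 * qx * qy + 2 * qz * qw, 1 - 2 * qx^2 - 2 * qz^2, 2 * qy * qz - 2 * qx * qw,
    2 * qx * qz - 2 * qy * qw, 2 * qy * qz + 2 * qx * qw, 1 - 2 * qx^2 - 2 * qy^2),
    nrow = 3, byrow = TRUE)
}

#' Assemble a 4x4 affine transform from rotation and translation
#'
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation vector.
#' @return 4x4 matrix `[[R, t], [0, 0, 0, 1]]`.
#' @export
assemble_affine <- function(R, t) {
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  rbind(cbind(R, matrix(t, 3, 1)), c(0, 0, 0, 1))
}

#' @rdname assemble_affine
#' @param calib A [hand_eye_calibration()].
#' @export
calibration_transform <- function(calib)
  assemble_affine(quat_to_rotation(calib$q), calib$t)

#' Transform a camera-frame point into the robot base frame
#'
#' Homogeneous multiply `P_b' = T %*% P_c'` followed by de-homogenisation;
#' the output point is tagged with the base frame.  Units are preserved.
#'
#' @param p A [point3d()] tagged `"camera"`.
#' @param T 4x4 affine transform (camera -> base), e.g. from
#'   [calibration_transform()].
#' @return A [point3d()] tagged `"base"`.
#' @export
camera_to_base <- function(p, T) {
  if (!inherits(p, "point3d") || p$frame != "camera")
    stop("camera_to_base expects a camera-frame point3d")
  v <- T %*% homogeneous(p)
  point3d(v[1] / v[4], v[2] / v[4], v[3] / v[4], frame = "base",
          unit = p$unit)
}

# median of valid depths in a (2r+1)^2 patch around (u, v); NA if none
depth_patch_median <- function(depth_map, u, v, r = 2L) {
  H <- nrow(depth_map); W <- ncol(depth_map)
  ilo <- max(1, round(v) - r); ihi <- min(H, round(v) + r)
  jlo <- max(1, round(u) - r); jhi <- min(W, round(u) + r)
  if (ilo > ihi || jlo > jhi) return(NA_real_)
  vals <- depth_map[ilo:ihi, jlo:jhi]
  vals <- vals[is.finite(vals) & vals > 0]
  if (length(vals) == 0L) return(NA_real_)
  stats::median(vals)
}

#' Locate detected fruit in the robot base frame
#'
#' For each detection: box centre, depth lookup at the (rounded) centre
#' pixel, pinhole deprojection and hand-eye transform into the base frame.
#' A non-positive or missing depth reading falls back to the median of the
#' valid depths in a 5x5 patch around the centre; detections without any
#' valid depth are reported separately, not silently dropped.
#'
#' @param detections Data frame with xmin, ymin, xmax, ymax (pixels).
#' @param depth_map `H x W` matrix of depth readings in millimetres
#'   (RealSense convention); non-positive values mean "no reading".
#' @param K A [camera_intrinsics()].
#' @param calib A [hand_eye_calibration()].
#' @param patch_fallback Use the 5x5 median patch fallback (default TRUE).
#' @return List with `points` (list of base-frame [point3d()], unit matching
#'   the calibration), `centers` (pixel centres), and `invalid` (indices of
#'   detections without usable depth).
#' @export
locate_fruit <- function(detections, depth_map, K, calib,
                         patch_fallback = TRUE) {
  if (!is.matrix(depth_map)) stop("depth_map must be an H x W matrix")
  T <- calibration_transform(calib)
  scale <- if (calib$unit == "m") 1e-3 else 1
  pts <- list(); invalid <- integer(0)
  ctr <- box_center(detections)
  if (nrow(detections) == 0L)
    return(list(points = list(), centers = ctr, invalid = invalid))
  for (i in seq_len(nrow(detections))) {
    u <- ctr[i, 1]; v <- ctr[i, 2]
    ui <- min(ncol(depth_map), max(1L, round(u)))
    vi <- min(nrow(depth_map), max(1L, round(v)))
    z <- depth_map[vi, ui]
    if (!is.finite(z) || z <= 0) {
      z <- if (patch_fallback) depth_patch_median(depth_map, u, v) else NA
    }
    if (!is.finite(z) || z <= 0) {
      invalid <- c(invalid, i)
      pts[i] <- list(NULL)
      next
    }
    pc <- deproject(u, v, z * scale, K, unit = calib$unit)
    pts[[i]] <- camera_to_base(pc, T)
  }
  list(points = pts, centers = ctr, invalid = invalid)
}

#' Simulate an RGB-D observation of known fruit positions
#'
#' Renders a depth map of spherical fruit at given base-frame positions as
#' seen by a pinhole camera under a hand-eye calibration: the test harness
#' for the localization pipeline (project, render depth, then invert with
#' [locate_fruit()]).
#'
#' @param points_base List of base-frame [point3d()] (unit of `calib`).
#' @param K A [camera_intrinsics()].
#' @param calib A [hand_eye_calibration()].
#' @param width,height Depth image size in pixels.
#' @param radius_px Rendered fruit radius in pixels.
#' @param depth_noise_sd Gaussian noise added to depth readings, in mm.
#' @return List with `depth` (mm matrix), `pixels` (projected centres),
#'   `boxes` (data frame of per-fruit pixel boxes).
#' @export
simulate_rgbd <- function(points_base, K, calib, width = 640L, height = 480L,
                          radius_px = 10, depth_noise_sd = 0) {
  T <- calibration_transform(calib)
  Ti <- solve(T)
  to_mm <- if (calib$unit == "m") 1e3 else 1
  depth <- matrix(0, nrow = height, ncol = width)
  px <- matrix(NA_real_, length(points_base), 2)
  boxes <- data.frame(xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0))
  for (i in seq_along(points_base)) {
    p <- points_base[[i]]
    v <- Ti %*% c(p$x, p$y, p$z, 1)
    xc <- v[1]; yc <- v[2]; zc <- v[3]
    if (zc <= 0) next
    u <- K$fx * xc / zc + K$cx
    vpx <- K$fy * yc / zc + K$cy
    px[i, ] <- c(u, vpx)
    ii <- max(1L, round(vpx - radius_px)):min(height, round(vpx + radius_px))
    jj <- max(1L, round(u - radius_px)):min(width, round(u + radius_px))
    for (r in ii) for (cc in jj) {
      if ((r - vpx)^2 + (cc - u)^2 <= radius_px^2) {
        z <- zc * to_mm
        if (depth_noise_sd > 0) z <- z + stats::rnorm(1, 0, depth_noise_sd)
        if (depth[r, cc] == 0 || z < depth[r, cc]) depth[r, cc] <- z
      }
    }
    boxes <- rbind(boxes, data.frame(xmin = u - radius_px,
                                     ymin = vpx - radius_px,
                                     xmax = u + radius_px,
                                     ymax = vpx + radius_px))
  }
  list(depth = depth, pixels = px, boxes = boxes)
}

#' Read/write calibration and intrinsics YAML files
#'
#' @param path File path.
#' @return For readers, the corresponding object.
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  hand_eye_calibration(c(y$qw, y$qx, y$qy, y$qz), c(y$tx, y$ty, y$tz),
                       unit = y$unit)
}

#' @rdname read_calibration
#' @param calib A [hand_eye_calibration()].
#' @export
write_calibration <- function(calib, path) {
  yaml::write_yaml(list(qw = calib$q[1], qx = calib$q[2], qy = calib$q[3],
                        qz = calib$q[4], tx = calib$t[1], ty = calib$t[2],
                        tz = calib$t[3], unit = calib$unit), path,
                   precision = 12L)
}

#' @rdname read_calibration
#' @export
read_intrinsics <- function(path) {
  y <- yaml::read_yaml(path)
  camera_intrinsics(y$fx, y$fy, y$cx, y$cy)
}

#' @rdname read_calibration
#' @param K A [camera_intrinsics()].
#' @export
write_intrinsics <- function(K, path)
  yaml::write_yaml(list(fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy), path)
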