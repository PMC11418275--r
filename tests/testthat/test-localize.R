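# Pinhole deprojection, quaternion/affine algebra and the simulated-camera
# localization round trip.

test_that("deprojection follows the pinhole model", {
  K <- camera_intrinsics(600, 580, 320, 240)
  p <- deproject(320, 240, 1.0, K)
  expect_equal(c(p$x, p$y, p$z), c(0, 0, 1))
  expect_equal(p$frame, "camera")

  K1 <- camera_intrinsics(1, 1, 0, 0)
  p2 <- deproject(2, 3, 1, K1)
  expect_equal(c(p2$x, p2$y, p2$z), c(2, 3, 1))
  # doubling depth doubles x and y
  pa <- deproject(400, 300, 1, K)
  pb <- deproject(400, 300, 2, K)
  expect_equal(c(pb$x, pb$y), 2 * c(pa$x, pa$y))
  expect_error(deproject(1, 1, 0, K), "positive")
  expect_error(camera_intrinsics(-1, 1, 0, 0), "positive")
})

test_that("quaternion-to-rotation reproduces the canonical matrices", {
  expect_equal(quat_to_rotation(c(1, 0, 0, 0)), diag(3))
  expect_equal(quat_to_rotation(c(0, 0, 0, 1)), diag(c(-1, -1, 1)))
  expect_equal(quat_to_rotation(c(sqrt(2) / 2, 0, 0, sqrt(2) / 2)),
               matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE),
               tolerance = 1e-12)
  expect_error(quat_to_rotation(c(0, 0, 0, 0)), "norm")
})

test_that("rotations are orthonormal with unit determinant; double cover holds", {
  set.seed(17)
  for (i in 1:50) {
    q <- rnorm(4)
    R <- quat_to_rotation(q)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    expect_equal(quat_to_rotation(-q), R, tolerance = 1e-12)
  }
})

test_that("affine assembly and inversion round-trip to machine precision", {
  expect_equal(assemble_affine(diag(3), c(0, 0, 0)), diag(4))
  T1 <- assemble_affine(diag(3), c(1, 2, 3))
  expect_equal(as.numeric(T1 %*% c(5, 6, 7, 1)), c(6, 8, 10, 1))
  set.seed(23)
  for (i in 1:20) {
    R <- quat_to_rotation(rnorm(4))
    t <- rnorm(3)
    T <- assemble_affine(R, t)
    expect_equal(T[4, ], c(0, 0, 0, 1))
    Tinv <- assemble_affine(t(R), -t(R) %*% t)   # closed-form inverse
    expect_lt(max(abs(T %*% Tinv - diag(4))), 1e-12)
  }
})

test_that("camera_to_base transforms, retags and enforces the frame tag", {
  p <- point3d(0.1, 0.2, 0.3, "camera")
  out <- camera_to_base(p, diag(4))
  expect_equal(c(out$x, out$y, out$z), c(0.1, 0.2, 0.3))
  expect_equal(out$frame, "base")
  tr <- camera_to_base(p, assemble_affine(diag(3), c(1, 1, 1)))
  expect_equal(c(tr$x, tr$y, tr$z), c(1.1, 1.2, 1.3))
  expect_error(camera_to_base(out, diag(4)), "camera-frame")
  # round trip through T then its inverse recovers the input
  set.seed(3)
  R <- quat_to_rotation(rnorm(4)); t <- rnorm(3)
  T <- assemble_affine(R, t)
  back <- camera_to_base(point3d(camera_to_base(p, T)$x,
                                 camera_to_base(p, T)$y,
                                 camera_to_base(p, T)$z, "camera"),
                         assemble_affine(t(R), -t(R) %*% t))
  expect_equal(c(back$x, back$y, back$z), c(p$x, p$y, p$z),
               tolerance = 1e-12)
})

test_that("render-then-invert recovers simulated fruit positions", {
  set.seed(41)
  K <- camera_intrinsics(600, 600, 160, 120)
  for (i in 1:10) {
    calib <- hand_eye_calibration(rnorm(4), runif(3, -0.5, 0.5), "m")
    Tm <- calibration_transform(calib)
    cam_pts <- lapply(1:2, function(j)
      point3d(runif(1, -0.1, 0.1), runif(1, -0.08, 0.08),
              runif(1, 0.6, 1.6), "camera"))
    base_pts <- lapply(cam_pts, camera_to_base, T = Tm)
    sim <- simulate_rgbd(base_pts, K, calib, 320, 240, radius_px = 5)
    det <- sim$boxes
    det$score <- 1
    loc <- locate_fruit(det, sim$depth, K, calib)
    expect_length(loc$invalid, 0L)
    for (j in 1:2) {
      err <- max(abs(c(loc$points[[j]]$x - base_pts[[j]]$x,
                       loc$points[[j]]$y - base_pts[[j]]$y,
                       loc$points[[j]]$z - base_pts[[j]]$z)))
      expect_lt(err, 1e-6)
    }
  }
})

test_that("degenerate localization inputs are reported, not dropped", {
  K <- camera_intrinsics(600, 600, 160, 120)
  calib <- hand_eye_calibration(c(1, 0, 0, 0), c(0, 0, 0), "m")
  empty <- locate_fruit(data.frame(xmin = numeric(0), ymin = numeric(0),
                                   xmax = numeric(0), ymax = numeric(0)),
                        matrix(1000, 240, 320), K, calib)
  expect_length(empty$points, 0L)
  # no depth anywhere: detection flagged invalid
  det <- data.frame(xmin = 100, ymin = 100, xmax = 140, ymax = 140)
  miss <- locate_fruit(det, matrix(0, 240, 320), K, calib)
  expect_equal(miss$invalid, 1L)
  # zero centre depth with valid neighbours: 5x5 median patch fallback
  dm <- matrix(1000, 240, 320)
  dm[120, 120] <- 0
  det2 <- data.frame(xmin = 100, ymin = 100, xmax = 140, ymax = 140)
  ok <- locate_fruit(det2, dm, K, calib)
  expect_length(ok$invalid, 0L)
  expect_equal(ok$points[[1]]$z, 1.0)    # mm converted to calibration metres
  # fallback can be disabled
  off <- locate_fruit(det2, dm, K, calib, patch_fallback = FALSE)
  expect_equal(off$invalid, 1L)
})

test_that("two fruit at distinct depths keep their simulated depth order", {
  K <- camera_intrinsics(600, 600, 160, 120)
  calib <- hand_eye_calibration(c(1, 0, 0, 0), c(0, 0, 0), "m")
  pts <- list(point3d(-0.1, 0, 0.8, "base"), point3d(0.1, 0, 1.4, "base"))
  sim <- simulate_rgbd(pts, K, calib, 320, 240, radius_px = 6)
  det <- sim$boxes; det$score <- 1
  loc <- locate_fruit(det, sim$depth, K, calib)
  expect_lt(loc$points[[1]]$z, loc$points[[2]]$z)
})

test_that("calibration and intrinsics files round-trip through YAML", {
  tmp <- tempfile(fileext = ".yaml")
  calib <- hand_eye_calibration(c(0.9, 0.1, -0.2, 0.3), c(0.5, -0.2, 0.8),
                                "m")
  write_calibration(calib, tmp)
  back <- read_calibration(tmp)
  expect_equal(back$q, calib$q, tolerance = 1e-12)
  expect_equal(back$t, calib$t)
  expect_equal(back$unit, "m")
  K <- camera_intrinsics(600, 580, 320, 240)
  write_intrinsics(K, tmp)
  expect_equal(read_intrinsics(tmp), K)
})
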