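test_that("pinhole projection follows similar triangles and distortion round-trips", {
  cam <- pinholeCamera(fx = 1000, cx = 500, cy = 500, width = 1001, height = 1001)
  # optical-axis points map to the principal point at any depth
  expect_equal(unname(projectPoint(cam, c(0, 0, 123))), matrix(c(500, 500), 1))
  expect_equal(unname(projectPoint(cam, c(10, 0, 100))), matrix(c(600, 500), 1))
  expect_error(projectPoint(cam, c(0, 0, -1)), "depth")

  # project / back-project round trip, with and without distortion
  camd <- pinholeCamera(fx = 1000, fy = 980, cx = 480, cy = 520,
                        width = 1001, height = 1001,
                        dist = c(-0.1, 0.02, 0, 1e-4, -2e-4))
  pts <- withr::with_seed(11, cbind(runif(50, -30, 30), runif(50, -30, 30),
                                    runif(50, 80, 300)))
  for (cc in list(cam, camd)) {
    pix <- projectPoint(cc, pts)
    rays <- pixelRay(cc, pix)
    rec <- rays * pts[, 3]     # scale each ray to the true depth
    expect_lt(max(abs(rec - pts)), 1e-9)
  }
})

test_that("rectified triangulation inverts projection and scales inversely with disparity", {
  cam <- pinholeCamera(fx = 1315, fy = 1315, cx = 1103.5, cy = 620.5,
                       width = 2208, height = 1242)
  rig <- stereoRig(cam, baseline = 45)
  p <- triangulateRectified(rig, c(1103.5, 620.5), 236.7)
  expect_equal(unname(p[1, 3]), 250.0, tolerance = 0.1 / 250)

  pts <- withr::with_seed(2, cbind(runif(20, -40, 40), runif(20, -20, 20),
                                   runif(20, 160, 340)))
  pixL <- projectPoint(rig@left, pts)
  pixR <- projectPoint(rig@right, applyTransform(rigidTransform(rig@R, rig@T), pts))
  disp <- pixL[, 1] - pixR[, 1]
  rec <- triangulateRectified(rig, pixL, disp)
  expect_lt(max(abs(rec - pts)), 1e-6)
  # doubling the disparity exactly halves the depth
  expect_equal(triangulateRectified(rig, c(1103.5, 620.5), 2 * 236.7)[1, 3],
               p[1, 3] / 2)
  expect_error(triangulateRectified(rig, c(0, 0), -3), "disparity")
})

test_that("reconstruction resolution follows the geometric formulas", {
  cam <- pinholeCamera(fx = 500, fy = 500, cx = 499.5, cy = 499.5,
                       width = 1000, height = 1000)  # FOV_H = 90 deg
  rig <- stereoRig(cam, baseline = 45, workingRange = c(50, 400))
  res <- reconstructionResolution(rig, 100)
  expect_equal(unname(res["dx"]), 0.2, tolerance = 1e-12)  # tan(45 deg) = 1

  cam2 <- pinholeCamera(fx = 1000, cx = 500, cy = 500, width = 1001, height = 1001)
  rig2 <- stereoRig(cam2, baseline = 45, workingRange = c(100, 400))
  expect_equal(unname(reconstructionResolution(rig2, 250)["dz"]),
               250^2 / (1000 * 45), tolerance = 1e-12)  # = 1.3889 mm
  # dx, dy linear in D; dz quadratic; all positive
  r1 <- reconstructionResolution(rig2, 150)
  r2 <- reconstructionResolution(rig2, 300)
  expect_equal(unname(r2[c("dx", "dy")] / r1[c("dx", "dy")]), c(2, 2))
  expect_equal(unname(r2["dz"] / r1["dz"]), 4)
  expect_true(all(r1 > 0))
  expect_warning(reconstructionResolution(rig2, 50), "outside")
})

test_that("rectification aligns rows of a converged rig and is identity on a parallel one", {
  img <- withr::with_seed(3, matrix(runif(120 * 160), 120, 160))
  cam <- pinholeCamera(fx = 200, fy = 200, cx = 79.5, cy = 59.5,
                       width = 160, height = 120)
  par <- stereoRig(cam, baseline = 45)
  out <- rectifyPair(img, img, par)
  expect_equal(dim(out$left), dim(img))
  expect_lt(max(abs(out$Hl - diag(3))), 1e-9)

  # rig with 2 degrees of relative yaw
  R <- rotationMatrix(c(0, 1, 0), 2)
  rig <- stereoRig(cam, baseline = 45, R = R,
                   T = drop(R %*% c(-45, 0, 0)))
  pts <- withr::with_seed(4, cbind(runif(20, -30, 30), runif(20, -20, 20),
                                   runif(20, 150, 350)))
  pixL <- projectPoint(rig@left, pts)
  pixR <- projectPoint(rig@right, applyTransform(rigidTransform(rig@R, rig@T), pts))
  res <- rectifyPair(img, img, rig)
  toNew <- function(H, p) {
    q <- cbind(p, 1) %*% t(H)
    q[, 1:2] / q[, 3]
  }
  rowErr <- abs(toNew(res$Hl, pixL)[, 2] - toNew(res$Hr, pixR)[, 2])
  expect_lt(max(rowErr), 0.1)
  expect_identical(res$rig@R, diag(3))
})

test_that("NCC disparity recovers a constructed shift and masks invalid pixels", {
  set.seed(5)
  H <- 60; W <- 110
  base <- matrix(runif(H * (W + 7)), H, W + 7)
  left <- base[, 1:W]
  right <- base[, 8:(W + 7)]   # scene shifts left in the right view: d = +7
  d <- disparityNCC(left, right, window = 9L, searchRange = c(0L, 15L))
  expect_equal(median(d$disparity, na.rm = TRUE), 7, tolerance = 0.1 / 7)

  same <- disparityNCC(left, left, window = 9L, searchRange = c(0L, 15L))
  expect_equal(median(same$disparity, na.rm = TRUE), 0, tolerance = 1e-8)

  flat <- matrix(0.5, H, W)
  dun <- disparityNCC(flat, flat, window = 9L, searchRange = c(0L, 15L))
  expect_true(all(is.na(dun$disparity)))
  expect_error(disparityNCC(left, right, window = 8L), "odd")
  expect_error(disparityNCC(left, right, searchRange = c(0L, 400L)), "search")
})

test_that("ray-plane intersection satisfies both constraints and rejects parallels", {
  pl <- plane3d(c(0, 0, 1), 100)
  expect_equal(drop(rayPlaneIntersect(c(0, 0, 0), c(0, 0, 1), pl)), c(0, 0, 100))
  expect_error(rayPlaneIntersect(c(0, 0, 0), c(1, 0, 0), pl), "parallel")

  # intersect camera rays with a tilted plane, re-project, recover pixels
  cam <- pinholeCamera(fx = 800, cx = 400, cy = 300, width = 801, height = 601)
  pl2 <- plane3d(c(0.2, -0.1, 1), 210)
  pix <- withr::with_seed(6, cbind(runif(30, 0, 800), runif(30, 0, 600)))
  rays <- pixelRay(cam, pix)
  pts <- rayPlaneIntersect(c(0, 0, 0), rays, pl2)
  expect_lt(max(abs(planeDistance(pl2, pts))), 1e-9)
  expect_lt(max(abs(projectPoint(cam, pts) - pix)), 1e-9)
})

test_that("projector calibration recovers a synthetic projector and reports honest residuals", {
  proj <- projectorModel(
    pinholeCamera(fx = 900, fy = 905, cx = 420, cy = 230,
                  width = 854, height = 480),
    R = rotationMatrix(c(0.2, 1, 0.1), 6), T = c(-50, 3, 8))
  # corners on three calibration plane poses (ray-plane style geometry)
  pts <- withr::with_seed(7, {
    do.call(rbind, lapply(1:3, function(v) {
      g <- expand.grid(x = seq(-50, 50, by = 20), y = seq(-30, 30, by = 20))
      z <- 200 + 30 * v + 0.2 * v * g$x - 0.1 * v * g$y
      cbind(g$x, g$y, z)
    }))
  })
  pix <- projectPoint(proj@intrinsics,
                      sweep(pts %*% t(proj@R), 2, proj@T, "+"))
  fit <- calibrateProjector(pts, pix, 854, 480)
  expect_lt(abs(fit@intrinsics@fx - 900) / 900, 0.001)
  expect_lt(abs(fit@intrinsics@fy - 905) / 905, 0.001)
  expect_lt(max(abs(fit@T - proj@T)), 0.01)
  expect_lt(max(abs(fit@R - proj@R)), 2e-4)  # ~0.01 degrees
  expect_lt(attr(fit, "rms"), 1e-6)

  # with 0.2 px corner noise the reported RMS stays near the noise floor
  pixn <- pix + withr::with_seed(8, matrix(rnorm(length(pix), sd = 0.2),
                                           ncol = 2))
  fitn <- calibrateProjector(pts, pixn, 854, 480)
  expect_lt(attr(fitn, "rms"), 3 * 0.2)
  # self-consistency: re-projection with the fitted model reproduces rms
  pp <- sweep(pts %*% t(fitn@R), 2, fitn@T, "+")
  rms2 <- sqrt(mean(rowSums((projectPoint(fitn@intrinsics, pp) - pixn)^2)))
  expect_equal(rms2, attr(fitn, "rms"), tolerance = 1e-9)

  # one single plane of points is rank-deficient
  one <- pts[1:20, ]; one[, 3] <- 250
  expect_error(calibrateProjector(one, pix[1:20, ], 854, 480), "coplanar")
})

test_that("calibration configs load from YAML and JSON with matching rigs", {
  dir <- withr::local_tempdir()
  cfg <- list(
    left = list(fx = 1316, fy = 1316, cx = 1103.5, cy = 620.5,
                width = 2208, height = 1242),
    right = list(fx = 1316, fy = 1316, cx = 1103.5, cy = 620.5,
                 width = 2208, height = 1242),
    baseline_mm = 45,
    R = diag(3), T = c(-45, 0, 0), working_range_mm = c(150, 350),
    projector = list(fx = 900, fy = 900, cx = 426.5, cy = 239.5,
                     width = 854, height = 480, R = diag(3),
                     T = c(50, 0, 0)))
  fy <- file.path(dir, "rig.yaml")
  yaml::write_yaml(cfg, fy)
  fj <- file.path(dir, "rig.json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE, digits = NA)
  ry <- readCalibration(fy)
  rj <- readCalibration(fj)
  for (rig in list(ry, rj)) {
    expect_s4_class(rig, "StereoRig")
    expect_equal(rig@baseline, 45)
    expect_equal(rig@left@fx, 1316)
    proj <- attr(rig, "projector")
    expect_s4_class(proj, "ProjectorModel")
    expect_equal(proj@T, c(50, 0, 0))
  }
})
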