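projectBoth <- function(rig, pts, noise = 0, seed = NULL) {
  pixL <- projectPoint(rig@left, pts)
  pixR <- projectPoint(rig@right, applyTransform(rigidTransform(rig@R, rig@T), pts))
  if (noise > 0) {
    withr::with_seed(seed %||% 1, {
      pixL <- pixL + matrix(rnorm(length(pixL), sd = noise), ncol = 2)
      pixR <- pixR + matrix(rnorm(length(pixR), sd = noise), ncol = 2)
    })
  }
  list(L = pixL, R = pixR)
}

test_that("fiducial triangulation round-trips and degrades gracefully with pixel noise", {
  rig <- testRig()
  fid <- markerFiducials(c(15, 5, 250))
  px <- projectBoth(rig, fid)
  rec <- triangulateFiducials(px$L, px$R, rig)
  expect_lt(max(abs(rec - fid)), 1e-6)

  # 0.2 px noise at 250 mm: per-fiducial 3D error below 1.5 mm (MC)
  errs <- vapply(1:50, function(k) {
    pxn <- projectBoth(rig, fid, noise = 0.2, seed = k)
    max(sqrt(rowSums((triangulateFiducials(pxn$L, pxn$R, rig) - fid)^2)))
  }, numeric(1))
  expect_lt(mean(errs), 1.5)

  expect_error(triangulateFiducials(px$L[1:2, ], px$R[1:2, ], rig), ">= 3")
})

test_that("least-squares rigid alignment is exact, proper, and locally optimal", {
  fid <- markerFiducials(c(0, 0, 200))
  tf0 <- rigidLsq(fid, fid)
  expect_lt(max(abs(tf0@R - diag(3))), 1e-12)
  expect_lt(max(abs(tf0@T)), 1e-12)
  expect_lt(attr(tf0, "rms"), 1e-12)

  withr::with_seed(21, {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- rotationMatrix(ax, 30)
    T <- c(5, -3, 10)
    moved <- applyTransform(rigidTransform(R, T), fid)
    tf <- rigidLsq(fid, moved)
    expect_lt(max(abs(tf@R - R)), 1e-9)
    expect_lt(max(abs(tf@T - T)), 1e-9)
    expect_equal(det(tf@R), 1, tolerance = 1e-12)

    # with noise the solution beats random small perturbations of itself
    noisy <- moved + matrix(rnorm(length(moved), sd = 0.1), ncol = 3)
    tfn <- rigidLsq(fid, noisy)
    res0 <- sum((applyTransform(tfn, fid) - noisy)^2)
    worse <- vapply(1:100, function(k) {
      dR <- rotationMatrix(rnorm(3), rnorm(1, sd = 0.2))
      p <- applyTransform(rigidTransform(tfn@R %*% dR,
                                         tfn@T + rnorm(3, sd = 0.02)), fid)
      sum((p - noisy)^2)
    }, numeric(1))
    expect_true(all(res0 <= worse + 1e-12))
  })

  line <- cbind(1:5, 2 * (1:5), 250 + 3 * (1:5))
  expect_error(rigidLsq(line, line), "collinear")
  # a reflection-inducing noisy case still returns det +1
  withr::with_seed(22, {
    a <- matrix(rnorm(9), 3); b <- matrix(rnorm(9), 3)
    expect_equal(det(rigidLsq(a, b)@R), 1, tolerance = 1e-9)
  })
})

test_that("overlay rendering lights the right pixels and clips behind the projector", {
  proj <- testProjector()
  cam <- proj@intrinsics
  # a point on the projector's optical axis lights the principal point
  axisPt <- drop(t(proj@R) %*% (c(0, 0, 150) - proj@T))
  img <- renderProjectorOverlay(matrix(axisPt, 1), proj, style = "points")
  expect_true(img[round(cam@cy) + 1, round(cam@cx) + 1])

  # ray cast from a lit pixel hits the generating point
  pt <- matrix(c(10, -5, 220), 1)
  img2 <- renderProjectorOverlay(pt, proj, style = "points")
  pix <- attr(img2, "projected")
  ray <- pixelRay(cam, pix)       # in projector frame
  pp <- sweep(pt %*% t(proj@R), 2, proj@T, "+")
  rec <- ray * pp[1, 3]
  back <- sweep(rec, 2, proj@T) %*% proj@R   # R^-1 (x - T)
  expect_lt(max(abs(back - pt)), 1e-6)

  expect_warning(img3 <- renderProjectorOverlay(matrix(c(0, 0, -100), 1), proj),
                 "behind")
  expect_false(any(img3))
})

test_that("the inter-visit AR chain reproduces an unchanged perimeter and is pose invariant", {
  rig <- testRig()
  proj <- testProjector()
  fid <- markerFiducials(c(14, 0, 200))
  th <- seq(0, 2 * pi, length.out = 120)[-120]
  perim <- cbind(6 * cos(th), 6 * sin(th), 200)
  skin <- plane3d(c(0, 0, 1), 200)

  overlayError <- function(noise, seedBase, moveTf = NULL) {
    fidCurr <- fid; perimCurr <- perim; skinCurr <- skin
    if (!is.null(moveTf)) {
      fidCurr <- applyTransform(moveTf, fid)
      perimCurr <- applyTransform(moveTf, perim)
      nC <- drop(moveTf@R %*% skin@n0)
      skinCurr <- plane3d(nC, skin@d0 + sum(nC * moveTf@T))
    }
    pxPrev <- projectBoth(rig, fid, noise = noise, seed = seedBase)
    pxCurr <- projectBoth(rig, fidCurr, noise = noise, seed = seedBase + 1000)
    res <- arCompare(pxPrev$L, pxPrev$R, pxCurr$L, pxCurr$R, perim, rig, proj,
                     style = "polyline")
    lit <- which(res$overlay, arr.ind = TRUE)
    rays <- pixelRay(proj@intrinsics, cbind(lit[, 2] - 1, lit[, 1] - 1))
    raysRef <- rays %*% proj@R    # R^-1 dir (R orthonormal)
    orig <- drop(-t(proj@R) %*% proj@T)
    hits <- rayPlaneIntersect(orig, raysRef, skinCurr)
    ctr <- colMeans(perimCurr)
    d <- sqrt(rowSums(sweep(hits, 2, ctr)^2))   # distance from centre
    mean(abs(d - 6))                            # deviation from the rim circle
  }

  # noiseless, unchanged scene: overlay coincides with the current rim
  # (residual is projector-pixel rasterization)
  e0 <- overlayError(0, 1)
  expect_lt(e0, 0.3)

  # 0.2 px fiducial noise: mean error below 1 mm
  en <- mean(vapply(1:20, function(k) overlayError(0.2, 2000 + 7 * k),
                    numeric(1)))
  expect_lt(en, 1)

  # scene rigidly moved between visits: error essentially unchanged
  mv <- rigidTransform(rotationMatrix(c(0.3, 1, 0), 10), c(12, -8, 14))
  em <- mean(vapply(1:20, function(k) overlayError(0.2, 4000 + 7 * k, mv),
                    numeric(1)))
  expect_lt(abs(em - en), 0.1 * max(en, 0.3) + 0.05)

  # marker mismatch is refused
  pxA <- projectBoth(rig, fid)
  pxB <- projectBoth(rig, fid[1:4, ])
  expect_error(arCompare(pxA$L, pxA$R, pxB$L, pxB$R, perim, rig, proj),
               "mismatch")
})

test_that("overlay error grows monotonically with fiducial noise", {
  rig <- testRig()
  fid <- markerFiducials(c(14, 0, 200))
  th <- seq(0, 2 * pi, length.out = 90)[-90]
  perim <- cbind(6 * cos(th), 6 * sin(th), 200)
  regErr <- function(noise) {
    mean(vapply(1:30, function(k) {
      pxP <- projectBoth(rig, fid, noise = noise, seed = 100 * k)
      pxC <- projectBoth(rig, fid, noise = noise, seed = 100 * k + 7)
      tf <- rigidLsq(triangulateFiducials(pxP$L, pxP$R, rig),
                     triangulateFiducials(pxC$L, pxC$R, rig))
      mean(sqrt(rowSums((applyTransform(tf, perim) - perim)^2)))
    }, numeric(1)))
  }
  errs <- vapply(c(0.05, 0.2, 0.8), regErr, numeric(1))
  expect_true(all(diff(errs) > 0))
})
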