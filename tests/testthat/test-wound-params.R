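test_that("total-least-squares skin plane recovers noisy planes and rejects degenerate input", {
  pts <- cbind(runif(100, -10, 10), runif(100, -10, 10), 10)
  pl <- fitSkinPlane(pts)
  expect_equal(abs(pl@n0[3]), 1, tolerance = 1e-9)
  expect_lt(attr(pl, "rms"), 1e-9)
  # orientation rule: normal towards the camera (-z)
  expect_lt(pl@n0[3], 0)

  base <- withr::with_seed(9, {
    g <- cbind(runif(1000, -20, 20), runif(1000, -20, 20))
    n <- c(0.1, -0.2, 1) / sqrt(1.05)
    d <- 150
    o <- d * n
    e1 <- c(1, 0, -n[1] / n[3]); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    sweep(g[, 1] %o% e1 + g[, 2] %o% e2, 2, o, "+") +
      rnorm(1000, sd = 0.5) %o% n
  })
  pl2 <- fitSkinPlane(base)
  expect_equal(attr(pl2, "rms"), 0.5, tolerance = 0.1)
  nTrue <- c(0.1, -0.2, 1) / sqrt(1.05)
  ang <- acos(min(1, abs(sum(pl2@n0 * nTrue))))
  expect_lt(ang * 180 / pi, 1)

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fitSkinPlane(line), "collinear|rank")
})

test_that("depth is the supremum of signed plane distance, clamped at zero", {
  mesh <- capMesh(r = 6, nth = 48, nph = 48)
  pl <- plane3d(c(0, 0, 1), 0)
  expect_equal(woundDepth(mesh, pl), 6, tolerance = 1e-3)
  # brute force over vertices equals the op exactly
  expect_identical(woundDepth(mesh, pl, orient = "asis"),
                   max(0, max(planeDistance(pl, meshVertices(mesh)))))
  # flat wound
  flat <- quadMesh(array(c(0, 1, 0, 1, 0, 0, 1, 1, rep(0, 4)), c(2, 2, 3)))
  expect_equal(woundDepth(flat, pl), 0)
})

test_that("Moore tracing closes the boundary with the expected pixel count", {
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(nrow(tracePerimeter2d(m1)), 1)

  for (wh in list(c(20, 10), c(7, 13), c(3, 3))) {
    m <- matrix(FALSE, 40, 40)
    m[10:(10 + wh[2] - 1), 5:(5 + wh[1] - 1)] <- TRUE
    b <- tracePerimeter2d(m)
    expect_equal(nrow(b), 2 * wh[1] + 2 * wh[2] - 4)
    # closed: first and last pixels are 8-neighbours
    expect_lte(max(abs(b[1, ] - b[nrow(b), ])), 1)
  }
  expect_error(tracePerimeter2d(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 20, 20); two[2:4, 2:4] <- TRUE; two[10:18, 10:18] <- TRUE
  expect_warning(b2 <- tracePerimeter2d(two), "largest")
  expect_equal(nrow(b2), 4 * 9 - 4)
})

test_that("lifted perimeter matches analytic circles and squares and scales exactly", {
  gc <- gridCloud(function(x, y) 0, ext = 22, spacing = 0.2)
  mC <- matrix(gc$x^2 + gc$y^2 < 400, gc$n, gc$n, byrow = TRUE)
  bC <- tracePerimeter2d(mC)
  pC <- perimeter3d(bC, gc$pixelMap, gc$points)
  expect_equal(pC, 2 * pi * 20, tolerance = 0.02)

  # 10 x 10 mm square in generic position w.r.t. the sampling grid
  mS <- matrix(abs(gc$x - 0.09) < 5 & abs(gc$y - 0.09) < 5, gc$n, gc$n,
               byrow = TRUE)
  bS <- tracePerimeter2d(mS)
  expect_equal(perimeter3d(bS, gc$pixelMap, gc$points), 40, tolerance = 0.02)

  expect_equal(perimeter3d(bC, gc$pixelMap, gc$points * 2), 2 * pC,
               tolerance = 1e-12)
  pmNA <- gc$pixelMap; pmNA[] <- NA
  expect_error(perimeter3d(bC, pmNA, gc$points), "fewer than 3")
})

test_that("quad-mesh 3D area matches closed forms and the triangulation oracle", {
  sq <- quadMesh(array(c(0, 1, 0, 1, 0, 0, 1, 1, rep(0, 4)), c(2, 2, 3)))
  expect_identical(area3d(sq), 1)

  mesh <- capMesh(r = 10, nth = 64, nph = 64)
  expect_equal(area3d(mesh), 2 * pi * 100, tolerance = 0.02)

  # independent oracle: sum of the two triangles of every quad
  triArea <- function(mesh) {
    tr <- meshTriangles(mesh)
    V <- tr$vertices; F <- tr$faces
    a <- V[F[, 2], ] - V[F[, 1], ]
    b <- V[F[, 3], ] - V[F[, 1], ]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    sum(sqrt(rowSums(cr^2))) / 2
  }
  expect_equal(area3d(sq), triArea(sq), tolerance = 1e-12)
  expect_equal(area3d(mesh), triArea(mesh), tolerance = 0.01)
})

test_that("alpha-shape projected area matches squares, disks and the hull bound", {
  gc <- gridCloud(function(x, y) 0, ext = 16, spacing = 0.2)
  pl <- plane3d(c(0, 0, 1), 0)
  inD <- gc$x^2 + gc$y^2 < 225
  aD <- projectedArea(gc$points[inD, ], pl)
  expect_equal(as.numeric(aD), pi * 225, tolerance = 0.02)

  xs <- seq(0.005, 0.995, by = 0.01)
  gs <- expand.grid(x = xs, y = xs)
  aS <- projectedArea(cbind(gs$x, gs$y, 0), pl)
  expect_equal(as.numeric(aS), 1, tolerance = 0.02)

  # convex cloud: alpha area below hull area, equal as alpha grows
  pts <- withr::with_seed(10, cbind(runif(800, -5, 5), runif(800, -4, 4), 0))
  hullIdx <- grDevices::chull(pts[, 1:2])
  hull <- pts[hullIdx, 1:2]
  hullArea <- abs(sum(hull[, 1] * c(hull[-1, 2], hull[1, 2]) -
                      hull[, 2] * c(hull[-1, 1], hull[1, 1]))) / 2
  aAlpha <- projectedArea(pts, pl, correction = FALSE)
  expect_lte(as.numeric(aAlpha), hullArea + 1e-9)
  aInf <- projectedArea(pts, pl, alpha = 1e6, correction = FALSE)
  expect_equal(as.numeric(aInf), hullArea, tolerance = 1e-6)

  # an alpha too small to cover every point is grown with a warning
  expect_warning(projectedArea(pts, pl, alpha = 0.05), "alpha grown")
})

test_that("main axes measure extents along principal directions, rotation-invariantly", {
  gc <- gridCloud(function(x, y) 0, ext = 12, spacing = 0.15)
  pl <- plane3d(c(0, 0, 1), 0)
  inR <- abs(gc$x) < 10 & abs(gc$y) < 5
  ax <- mainAxes(gc$points[inR, ], pl)
  expect_equal(ax$major, 20, tolerance = 0.02)
  expect_equal(ax$minor, 10, tolerance = 0.02)

  # same rectangle rotated 37 degrees in-plane
  R <- rotationMatrix(c(0, 0, 1), 37)
  axR <- mainAxes(gc$points[inR, ] %*% t(R), pl)
  expect_equal(axR$major, 20, tolerance = 0.02)
  expect_equal(axR$minor, 10, tolerance = 0.02)

  # isotropic disk: both axes equal within 3%
  inD <- gc$x^2 + gc$y^2 < 64
  axD <- mainAxes(gc$points[inD, ], pl)
  expect_lt(abs(axD$major / axD$minor - 1), 0.03)
  expect_error(mainAxes(matrix(c(1, 1, 0, 1, 1, 0), 2, 3, byrow = TRUE), pl),
               "zero-variance")
})

test_that("cavity volume matches the spherical cap and a Monte-Carlo oracle", {
  pl <- plane3d(c(0, 0, 1), 0)
  flat <- quadMesh(array(c(0, 1, 0, 1, 0, 0, 1, 1, rep(0, 4)), c(2, 2, 3)))
  expect_equal(woundVolume(flat, pl), 0)

  mesh <- capMesh(r = 6, nth = 64, nph = 64)
  expect_equal(woundVolume(mesh, pl), 2 / 3 * pi * 216, tolerance = 0.03)

  # Monte-Carlo oracle on a height-field mesh: sample the bounding box,
  # compare the inside fraction with the computed volume
  nG <- 40
  xs <- seq(-6, 6, length.out = nG)
  V <- array(0, c(nG, nG, 3))
  for (j in seq_len(nG)) {
    V[, j, 1] <- xs
    V[, j, 2] <- xs[j]
    V[, j, 3] <- sqrt(pmax(0, 36 - xs^2 - xs[j]^2))
  }
  hf <- quadMesh(V)
  vol <- woundVolume(hf, pl)
  mc <- withr::with_seed(11, {
    p <- cbind(runif(1e5, -6, 6), runif(1e5, -6, 6), runif(1e5, 0, 6))
    # bilinear interpolation of the height field at (x, y)
    ix <- pmin(pmax(findInterval(p[, 1], xs), 1), nG - 1)
    iy <- pmin(pmax(findInterval(p[, 2], xs), 1), nG - 1)
    tx <- (p[, 1] - xs[ix]) / diff(xs)[1]
    ty <- (p[, 2] - xs[iy]) / diff(xs)[1]
    Z <- V[, , 3]
    h <- (1 - ty) * ((1 - tx) * Z[cbind(ix, iy)] + tx * Z[cbind(ix + 1, iy)]) +
      ty * ((1 - tx) * Z[cbind(ix, iy + 1)] + tx * Z[cbind(ix + 1, iy + 1)])
    mean(p[, 3] < h) * 12 * 12 * 6
  })
  expect_equal(vol, mc, tolerance = 0.02)
})

test_that("parameters obey homogeneity and rigid invariance", {
  mesh <- capMesh(r = 5, nth = 40, nph = 40)
  pl <- plane3d(c(0, 0, 1), 0)
  V <- meshVertices(mesh)

  d1 <- woundDepth(mesh, pl); a1 <- area3d(mesh); v1 <- woundVolume(mesh, pl)
  ap1 <- as.numeric(projectedArea(V, pl, correction = FALSE))
  ax1 <- mainAxes(V, pl, correction = FALSE)

  # scale by 2: lengths x2, areas x4, volume x8
  mesh2 <- quadMesh(mesh@vertices * 2)
  V2 <- V * 2
  expect_equal(woundDepth(mesh2, pl), 2 * d1, tolerance = 1e-9)
  expect_equal(area3d(mesh2), 4 * a1, tolerance = 1e-9)
  expect_equal(woundVolume(mesh2, pl), 8 * v1, tolerance = 1e-9)
  expect_equal(as.numeric(projectedArea(V2, pl, correction = FALSE)), 4 * ap1,
               tolerance = 1e-9)
  ax2 <- mainAxes(V2, pl, correction = FALSE)
  expect_equal(ax2$major, 2 * ax1$major, tolerance = 1e-9)

  # rigid transform of mesh + plane together
  tf <- rigidTransform(rotationMatrix(c(1, 2, 3), 25), c(30, -12, 240))
  Vr <- applyTransform(tf, V)
  meshR <- quadMesh(array(Vr, dim(mesh@vertices)))
  nR <- drop(tf@R %*% pl@n0)
  plR <- plane3d(nR, pl@d0 + sum(nR * tf@T))
  expect_equal(woundDepth(meshR, plR), d1, tolerance = 1e-3 * d1)
  expect_equal(area3d(meshR), a1, tolerance = 1e-3 * a1)
  expect_equal(woundVolume(meshR, plR), v1, tolerance = 1e-3 * v1)
  expect_equal(as.numeric(projectedArea(Vr, plR, correction = FALSE)), ap1,
               tolerance = 1e-3 * ap1)
  axR <- mainAxes(Vr, plR, correction = FALSE)
  expect_equal(axR$major, ax1$major, tolerance = 1e-3)
  # surface area dominates its planar projection
  expect_gte(a1, ap1 - 1e-9)
})
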