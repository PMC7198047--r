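# Synthetic wound phantoms with analytic ground truth.
#
# Phantom frame: the skin is the plane z = 0 and the cavity depth is the
# height field z = d(x, y) >= 0, increasing away from the camera (which
# sits on the -z side looking towards +z). Ground-truth surface area is
# the area of the height-field graph over the footprint; vertical walls
# (possible at a cliff-like rim) are excluded, since a camera looking
# along -z cannot sample them.

#' Built-in wound phantoms
#'
#' Four analytic phantoms spanning the range of clinically reported
#' wound shapes:
#' \describe{
#'   \item{A}{small circular ulcer: hemispherical cavity (radius 6 mm),
#'     pure granulation.}
#'   \item{B}{trapezoidal footprint with a linear depth ramp from 0 to
#'     7.5 mm; granulation and slough.}
#'   \item{C}{elliptical ulcer (18 x 11 mm) with a half-ellipsoid cavity
#'     4 mm deep; granulation, slough and a necrotic core.}
#'   \item{D}{irregular ulcer: seeded random smooth boundary and bumpy
#'     depth field rescaled to a 5.4 mm maximum; slough and
#'     granulation.}
#' }
#' Ground truth is closed-form for A-C and high-resolution numerical
#' integration (about 10^6 samples) for D.
#'
#' @param name `"A"`, `"B"`, `"C"` or `"D"`.
#' @param params optional list overriding the shape parameters
#'   (`radius`, `base1`, `base2`, `length`, `maxDepth`, `a`, `b`, ...).
#' @param seed integer seed for the randomized phantom D (default 7).
#' @return A [PhantomSpec-class].
#' @export
makePhantom <- function(name = c("A", "B", "C", "D"), params = list(),
                        seed = 7L) {
  name <- match.arg(name)
  switch(name,
         A = phantomCircular(params),
         B = phantomTrapezoid(params),
         C = phantomElliptical(params),
         D = phantomIrregular(params, seed))
}

phantomDomain <- function(halfx, halfy, margin = 1.45, pad = 2) {
  list(xlim = c(-halfx * margin - pad, halfx * margin + pad),
       ylim = c(-halfy * margin - pad, halfy * margin + pad))
}

phantomCircular <- function(params) {
  r <- params$radius %||% 6
  inside <- function(x, y) x^2 + y^2 < r^2
  depth <- function(x, y) ifelse(x^2 + y^2 < r^2,
                                 sqrt(pmax(0, r^2 - x^2 - y^2)), 0)
  tissue <- function(x, y) rep("granulation", length(x))
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  boundary <- cbind(r * cos(th), r * sin(th))
  truth <- woundReport(
    depth = r,
    perimeter = 2 * pi * r,
    area3d = 2 * pi * r^2,
    areaProjected = pi * r^2,
    axisMajor = 2 * r, axisMinor = 2 * r,
    volume = 2 / 3 * pi * r^3)
  new("PhantomSpec", name = "A", shape = "circular",
      params = list(radius = r), inside = inside, depth = depth,
      tissueMap = tissue, boundary = boundary,
      domain = phantomDomain(r, r), truth = truth, seed = NA_real_)
}

phantomTrapezoid <- function(params) {
  W1 <- params$base1 %||% 20     # wide base at y = -L/2
  W2 <- params$base2 %||% 12     # narrow base at y = +L/2
  L <- params$length %||% 18
  dmax <- params$maxDepth %||% 7.5
  halfw <- function(y) (W1 + (W2 - W1) * (y / L + 0.5)) / 2
  inside <- function(x, y) abs(y) < L / 2 & abs(x) < halfw(y)
  depth <- function(x, y) ifelse(inside(x, y), dmax * (y / L + 0.5), 0)
  tissue <- function(x, y) ifelse(x < 0, "granulation", "slough")
  boundary <- rbind(
    cbind(seq(-W1 / 2, W1 / 2, length.out = 200), -L / 2),
    cbind(seq(W1 / 2, W2 / 2, length.out = 200), seq(-L / 2, L / 2, length.out = 200)),
    cbind(seq(W2 / 2, -W2 / 2, length.out = 200), L / 2),
    cbind(seq(-W2 / 2, -W1 / 2, length.out = 200), seq(L / 2, -L / 2, length.out = 200)))
  side <- sqrt(L^2 + ((W1 - W2) / 2)^2)
  area <- (W1 + W2) / 2 * L
  truth <- woundReport(
    depth = dmax,
    perimeter = W1 + W2 + 2 * side,
    area3d = area * sqrt(1 + (dmax / L)^2),
    areaProjected = area,
    axisMajor = max(W1, L), axisMinor = min(W1, L),
    volume = dmax * L * (W1 / 2 + (W2 - W1) / 3))
  new("PhantomSpec", name = "B", shape = "trapezoidal_ramp",
      params = list(base1 = W1, base2 = W2, length = L, maxDepth = dmax),
      inside = inside, depth = depth, tissueMap = tissue,
      boundary = boundary, domain = phantomDomain(W1 / 2, L / 2),
      truth = truth, seed = NA_real_)
}

phantomElliptical <- function(params) {
  a <- params$a %||% 9
  b <- params$b %||% 5.5
  dmax <- params$maxDepth %||% 4
  inside <- function(x, y) (x / a)^2 + (y / b)^2 < 1
  depth <- function(x, y) {
    s <- 1 - (x / a)^2 - (y / b)^2
    ifelse(s > 0, dmax * sqrt(pmax(0, s)), 0)
  }
  tissue <- function(x, y) {
    s <- (x / a)^2 + (y / b)^2
    out <- ifelse(x < 0, "granulation", "slough")
    out[s < 0.16] <- "necrosis"
    out
  }
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  boundary <- cbind(a * cos(th), b * sin(th))
  # ellipse circumference by dense quadrature
  thd <- seq(0, 2 * pi, length.out = 200001)
  per <- sum(sqrt((a * sin(thd))^2 + (b * cos(thd))^2)[-1] * diff(thd))
  # cap surface area on the ellipsoid parameterization (theta from the
  # deepest point to the rim)
  nth <- 1200; nph <- 1200
  thg <- (seq_len(nth) - 0.5) / nth * (pi / 2)
  phg <- (seq_len(nph) - 0.5) / nph * (2 * pi)
  TH <- matrix(thg, nth, nph); PH <- matrix(phg, nth, nph, byrow = TRUE)
  # r(theta,phi) = (a sin t cos p, b sin t sin p, dmax cos t)
  rth <- array(c(a * cos(TH) * cos(PH), b * cos(TH) * sin(PH),
                 -dmax * sin(TH)), c(nth, nph, 3))
  rph <- array(c(-a * sin(TH) * sin(PH), b * sin(TH) * cos(PH),
                 0 * TH), c(nth, nph, 3))
  cx <- rth[, , 2] * rph[, , 3] - rth[, , 3] * rph[, , 2]
  cy <- rth[, , 3] * rph[, , 1] - rth[, , 1] * rph[, , 3]
  cz <- rth[, , 1] * rph[, , 2] - rth[, , 2] * rph[, , 1]
  surf <- sum(sqrt(cx^2 + cy^2 + cz^2)) * (pi / 2 / nth) * (2 * pi / nph)
  truth <- woundReport(
    depth = dmax,
    perimeter = per,
    area3d = surf,
    areaProjected = pi * a * b,
    axisMajor = 2 * max(a, b), axisMinor = 2 * min(a, b),
    volume = 2 / 3 * pi * a * b * dmax)
  new("PhantomSpec", name = "C", shape = "elliptical",
      params = list(a = a, b = b, maxDepth = dmax),
      inside = inside, depth = depth, tissueMap = tissue,
      boundary = boundary, domain = phantomDomain(a, b),
      truth = truth, seed = NA_real_)
}

phantomIrregular <- function(params, seed) {
  R0 <- params$radius %||% 8
  dmax <- params$maxDepth %||% 5.4
  co <- withSeed(seed, {
    k <- 2:5
    list(a = runif(4, -1, 1) * 0.12 / sqrt(k),
         b = runif(4, -1, 1) * 0.12 / sqrt(k),
         bumpx = runif(3, -0.4, 0.4) * R0,
         bumpy = runif(3, -0.4, 0.4) * R0,
         bumpc = runif(3, -0.35, 0.35),
         bumpw = runif(3, 2.0, 3.5))
  })
  Rtheta <- function(th) {
    out <- rep(1, length(th))
    for (i in 1:4)
      out <- out + co$a[i] * cos((i + 1) * th) + co$b[i] * sin((i + 1) * th)
    R0 * out
  }
  inside <- function(x, y) {
    th <- atan2(y, x)
    sqrt(x^2 + y^2) < Rtheta(th)
  }
  rawDepth <- function(x, y) {
    th <- atan2(y, x)
    s <- sqrt(x^2 + y^2) / Rtheta(th)
    base <- pmax(0, 1 - s^2)
    g <- rep(1, length(x))
    for (j in 1:3)
      g <- g + co$bumpc[j] *
        exp(-((x - co$bumpx[j])^2 + (y - co$bumpy[j])^2) / (2 * co$bumpw[j]^2))
    base * g
  }
  # rescale so the fine-grid maximum equals dmax (deterministic)
  h <- 0.025
  ext <- R0 * 1.5
  xs <- seq(-ext, ext, by = h)
  g <- expand.grid(x = xs, y = xs)
  isin <- inside(g$x, g$y)
  raw <- rawDepth(g$x, g$y) * isin
  scale <- dmax / max(raw)
  depth <- function(x, y) ifelse(inside(x, y),
                                 pmax(0, rawDepth(x, y)) * scale, 0)
  tissue <- function(x, y) {
    th <- atan2(y, x)
    ifelse(sin(2 * th) + 0.25 > 0, "granulation", "slough")
  }
  # ground truth by numerical integration on the fine grid
  d <- raw * scale
  areaP <- sum(isin) * h^2
  vol <- sum(d) * h^2
  nx <- length(xs)
  D <- matrix(d, nx, nx)          # [ix, iy] with x fastest
  dzdx <- (D[c(2:nx, nx), ] - D[c(1, 1:(nx - 1)), ]) / (2 * h)
  dzdy <- (D[, c(2:nx, nx)] - D[, c(1, 1:(nx - 1))]) / (2 * h)
  IN <- matrix(isin, nx, nx)
  a3 <- sum(sqrt(1 + dzdx[IN]^2 + dzdy[IN]^2)) * h^2
  thd <- seq(0, 2 * pi, length.out = 100001)
  Rv <- Rtheta(thd)
  dR <- c(diff(Rv) / diff(thd), NA)
  per <- sum(sqrt(Rv[-length(Rv)]^2 + dR[-length(dR)]^2) * diff(thd))
  # axes: PCA of the footprint region, extents of boundary projections
  xin <- g$x[isin]; yin <- g$y[isin]
  pcc <- prcomp(cbind(xin, yin))
  thb <- seq(0, 2 * pi, length.out = 4001)[-4001]
  bx <- Rtheta(thb) * cos(thb); by <- Rtheta(thb) * sin(thb)
  proj <- sweep(cbind(bx, by), 2, pcc$center) %*% pcc$rotation
  extents <- apply(proj, 2, function(v) diff(range(v)))
  truth <- woundReport(
    depth = dmax, perimeter = per, area3d = a3, areaProjected = areaP,
    axisMajor = max(extents), axisMinor = min(extents), volume = vol)
  boundary <- cbind(bx, by)
  new("PhantomSpec", name = "D", shape = "irregular",
      params = list(radius = R0, maxDepth = dmax, coeffs = co),
      inside = inside, depth = depth, tissueMap = tissue,
      boundary = boundary, domain = phantomDomain(max(Rv), max(Rv)),
      truth = truth, seed = seed)
}

#' Sample a device-like point cloud from a phantom
#'
#' Grid-samples the phantom height field at the reference camera's
#' lateral resolution, adds Gaussian depth noise (the dominant error
#' direction of disparity-based reconstruction), applies an optional
#' rigid pose and the working-distance offset, and emits the pixel
#' provenance map plus the true wound and skin masks.
#'
#' @param phantom a [PhantomSpec-class].
#' @param spacing lateral sample spacing (mm, default 0.2).
#' @param noiseSigma depth noise SD (mm, default 0.1).
#' @param pose optional [RigidTransform-class] applied to the points.
#' @param workingDistance added to z so the skin plane sits at this
#'   camera distance (mm, default 200).
#' @param seed RNG seed for the noise (NULL = current stream).
#' @return List: `cloud` ([WoundCloud-class]), `woundMask`, `skinMask`
#'   (logical H x W truth masks), `spacing`.
#' @export
sampleCloud <- function(phantom, spacing = 0.2, noiseSigma = 0.1,
                        pose = NULL, workingDistance = 200, seed = NULL) {
  xs <- seq(phantom@domain$xlim[1], phantom@domain$xlim[2], by = spacing)
  ys <- seq(phantom@domain$ylim[1], phantom@domain$ylim[2], by = spacing)
  W <- length(xs); H <- length(ys)
  g <- expand.grid(x = xs, y = ys)      # x fastest: index = ix + (iy-1) W
  z <- phantom@depth(g$x, g$y)
  if (noiseSigma > 0)
    z <- z + withSeed(seed, rnorm(length(z), sd = noiseSigma))
  pts <- cbind(g$x, g$y, z)
  if (!is.null(pose)) pts <- applyTransform(pose, pts)
  pts[, 3] <- pts[, 3] + workingDistance
  pixelMap <- matrix(seq_len(H * W), H, W, byrow = TRUE)
  woundMask <- matrix(phantom@inside(g$x, g$y), H, W, byrow = TRUE)
  list(cloud = woundCloud(pts, pixelMap),
       woundMask = woundMask, skinMask = !woundMask, spacing = spacing)
}

# default red/yellow/black tissue palette plus skin tone, sRGB in [0,1]
tissuePalette <- function() {
  list(granulation = c(0.70, 0.13, 0.13),
       slough = c(0.78, 0.60, 0.16),
       necrosis = c(0.10, 0.08, 0.07),
       skin = c(0.91, 0.76, 0.65))
}

#' Render the reference-camera image of a phantom
#'
#' Rasterizes the tissue map with the red/yellow/black clinical palette
#' on a skin-toned background, with optional multiplicative brightness
#' gradient (uneven illumination) and Gaussian pixel noise.
#'
#' @param phantom a [PhantomSpec-class].
#' @param spacing pixel pitch in mm (match the sampled cloud).
#' @param palette named list of RGB triplets (see `tissuePalette`).
#' @param brightnessSlope total relative brightness change across the
#'   image width (0 = flat illumination).
#' @param noiseSd per-channel Gaussian pixel noise SD (default 0.01).
#' @param seed RNG seed for the pixel noise.
#' @return List: `image` (H x W x 3 array in \[0,1\]), `tissueMasks`
#'   (named list of logical matrices partitioning the wound footprint).
#' @export
renderWoundImage <- function(phantom, spacing = 0.2,
                             palette = tissuePalette(),
                             brightnessSlope = 0, noiseSd = 0.01,
                             seed = NULL) {
  xs <- seq(phantom@domain$xlim[1], phantom@domain$xlim[2], by = spacing)
  ys <- seq(phantom@domain$ylim[1], phantom@domain$ylim[2], by = spacing)
  W <- length(xs); H <- length(ys)
  g <- expand.grid(x = xs, y = ys)
  isin <- phantom@inside(g$x, g$y)
  lab <- rep("skin", length(isin))
  lab[isin] <- phantom@tissueMap(g$x[isin], g$y[isin])
  img <- array(0, c(H, W, 3))
  for (k in 1:3) {
    v <- vapply(palette, `[`, numeric(1), k)[lab]
    img[, , k] <- matrix(v, H, W, byrow = TRUE)
  }
  if (brightnessSlope != 0) {
    bf <- matrix(1 + brightnessSlope * ((col(matrix(0, H, W)) - 1) / (W - 1) - 0.5),
                 H, W)
    for (k in 1:3) img[, , k] <- img[, , k] * bf
  }
  if (noiseSd > 0) {
    img <- img + withSeed(seed, array(rnorm(H * W * 3, sd = noiseSd),
                                      c(H, W, 3)))
  }
  img <- pmax(pmin(img, 1), 0)
  classes <- unique(lab[isin])
  masks <- lapply(classes, function(cl)
    matrix(lab == cl, H, W, byrow = TRUE))
  names(masks) <- classes
  list(image = img, tissueMasks = masks)
}

#' Coarse user contour for a phantom
#'
#' Emulates the clinician's rough tracing: the true footprint boundary,
#' expanded about its centroid and perturbed by smooth jitter, in pixel
#' coordinates of the sampled image.
#'
#' @param phantom a [PhantomSpec-class].
#' @param spacing pixel pitch (mm) of the target image.
#' @param expand radial expansion factor (default 1.15).
#' @param jitterSd smooth radial jitter SD as a fraction of the local
#'   radius (default 0.03).
#' @param nVertices polygon vertices (default 72).
#' @param seed RNG seed for the jitter.
#' @return M x 2 matrix of polygon vertices in 0-based pixels.
#' @export
coarseContour <- function(phantom, spacing = 0.2, expand = 1.15,
                          jitterSd = 0.03, nVertices = 72L, seed = NULL) {
  bnd <- phantom@boundary
  pick <- round(seq(1, nrow(bnd), length.out = nVertices + 1))[-(nVertices + 1)]
  P <- bnd[pick, , drop = FALSE]
  ctr <- colMeans(bnd)
  P <- sweep(sweep(P, 2, ctr) * expand, 2, ctr, "+")
  if (jitterSd > 0) {
    j <- withSeed(seed, rnorm(6, sd = jitterSd))
    th <- atan2(P[, 2] - ctr[2], P[, 1] - ctr[1])
    f <- 1 + j[1] * cos(th) + j[2] * sin(th) + j[3] * cos(2 * th) +
      j[4] * sin(2 * th) + j[5] * cos(3 * th) + j[6] * sin(3 * th)
    P <- sweep(sweep(P, 2, ctr) * f, 2, ctr, "+")
  }
  cbind((P[, 1] - phantom@domain$xlim[1]) / spacing,
        (P[, 2] - phantom@domain$ylim[1]) / spacing)
}
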