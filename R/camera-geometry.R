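#' Project 3D points through a pinhole camera
#'
#' Applies the pinhole projection `u = fx X/Z + cx`, `v = fy Y/Z + cy`,
#' with radial/tangential distortion applied in normalized coordinates
#' when the camera carries distortion coefficients.
#'
#' @param camera a [PinholeCamera-class].
#' @param points N x 3 matrix (or length-3 vector) in the camera frame
#'   (mm), +z forward.
#' @return N x 2 matrix of pixel coordinates `(u, v)`.
#' @export
projectPoint <- function(camera, points) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  Z <- points[, 3]
  if (any(Z <= 0)) stop("points must have positive depth (Z > 0)")
  x <- points[, 1] / Z
  y <- points[, 2] / Z
  if (length(camera@dist)) {
    d <- c(camera@dist, rep(0, 5))[1:5]
    r2 <- x^2 + y^2
    rad <- 1 + d[1] * r2 + d[2] * r2^2 + d[3] * r2^3
    xt <- 2 * d[4] * x * y + d[5] * (r2 + 2 * x^2)
    yt <- d[4] * (r2 + 2 * y^2) + 2 * d[5] * x * y
    xn <- x * rad + xt
    yn <- y * rad + yt
  } else {
    xn <- x; yn <- y
  }
  cbind(u = camera@fx * xn + camera@cx, v = camera@fy * yn + camera@cy)
}

#' Back-project pixels to unit-depth rays
#'
#' Returns, for each pixel, the direction of the camera ray through it
#' (unnormalized, with Z component 1). Distortion is inverted iteratively
#' when present.
#'
#' @param camera a [PinholeCamera-class].
#' @param pixels N x 2 matrix (or length-2 vector) of `(u, v)`.
#' @return N x 3 matrix of ray directions; the ray is `t * dir`, `t > 0`.
#' @export
pixelRay <- function(camera, pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, 1, 2)
  xd <- (pixels[, 1] - camera@cx) / camera@fx
  yd <- (pixels[, 2] - camera@cy) / camera@fy
  if (length(camera@dist)) {
    d <- c(camera@dist, rep(0, 5))[1:5]
    x <- xd; y <- yd
    for (i in 1:20) {
      r2 <- x^2 + y^2
      rad <- 1 + d[1] * r2 + d[2] * r2^2 + d[3] * r2^3
      xt <- 2 * d[4] * x * y + d[5] * (r2 + 2 * x^2)
      yt <- d[4] * (r2 + 2 * y^2) + 2 * d[5] * x * y
      x <- (xd - xt) / rad
      y <- (yd - yt) / rad
    }
    xd <- x; yd <- y
  }
  cbind(xd, yd, 1)
}

#' Triangulate a rectified stereo match
#'
#' For a rectified (parallel) rig, depth follows from the disparity as
#' `Z = f b / d`; X and Y follow from pinhole back-projection of the left
#' pixel at that depth.
#'
#' @param rig a rectified [StereoRig-class].
#' @param pixels N x 2 matrix of left-image pixels `(u, v)`.
#' @param disparity numeric vector of disparities (pixels), must be > 0.
#' @return N x 3 matrix of 3D points (mm) in the left camera frame.
#' @export
triangulateRectified <- function(rig, pixels, disparity) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, 1, 2)
  if (any(!is.finite(disparity)) || any(disparity <= 0))
    stop("invalid match: disparity must be finite and > 0")
  cam <- rig@left
  Z <- cam@fx * rig@baseline / disparity
  X <- (pixels[, 1] - cam@cx) * Z / cam@fx
  Y <- (pixels[, 2] - cam@cy) * Z / cam@fy
  cbind(X, Y, Z)
}

#' Reconstruction resolution of a stereo rig
#'
#' Lateral and depth resolution of the triangulated reconstruction at a
#' working distance `D`:
#' `dX = 2 D tan(FOV_H/2) / C_H`, `dY = 2 D tan(FOV_V/2) / C_V`,
#' `dZ = D^2 / (f b)`.
#'
#' @param rig a [StereoRig-class].
#' @param D working distance (mm). A warning is issued (and the value
#'   still computed) outside the rig's working range.
#' @return Named vector `c(dx, dy, dz)` in mm.
#' @export
reconstructionResolution <- function(rig, D) {
  if (D < rig@workingRange[1] || D > rig@workingRange[2])
    warning(sprintf("working distance %g mm outside range [%g, %g] mm",
                    D, rig@workingRange[1], rig@workingRange[2]))
  cam <- rig@left
  fov <- fieldOfView(cam) * pi / 180
  c(dx = 2 * D * tan(fov[["h"]] / 2) / cam@width,
    dy = 2 * D * tan(fov[["v"]] / 2) / cam@height,
    dz = D^2 / (cam@fx * rig@baseline))
}

# rectifying rotation for a rig: new x-axis along the baseline, new z as
# close as possible to the mean optical axis (Fusiello-style)
rectifyingRotation <- function(rig) {
  # optical centre of the right camera in the left frame: X_r = R X + T = 0
  C2 <- drop(-t(rig@R) %*% rig@T)
  b <- sqrt(sum(C2^2))
  if (b < 1e-9) stop("degenerate calibration: coincident camera centres")
  e1 <- C2 / b
  if (e1[1] < 0) e1 <- -e1
  zl <- c(0, 0, 1)                       # left optical axis
  zr <- drop(t(rig@R) %*% c(0, 0, 1))    # right optical axis in left frame
  zm <- (zl + zr) / 2
  e2 <- c(zm[2] * e1[3] - zm[3] * e1[2],
          zm[3] * e1[1] - zm[1] * e1[3],
          zm[1] * e1[2] - zm[2] * e1[1])   # zm x e1
  e2 <- e2 / sqrt(sum(e2^2))
  e2 <- -e2                               # y down convention
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  if (e3[3] < 0) { e2 <- -e2; e3 <- -e3 }
  rbind(e1, e2, e3)
}

# bilinear sampling of a grayscale matrix at (real) pixel coordinates
bilinearSample <- function(img, u, v) {
  H <- nrow(img); W <- ncol(img)
  u0 <- floor(u); v0 <- floor(v)
  du <- u - u0; dv <- v - v0
  ok <- u0 >= 0 & v0 >= 0 & u0 <= W - 2 & v0 <= H - 2
  out <- rep(NA_real_, length(u))
  i <- v0[ok] + 1; j <- u0[ok] + 1
  a <- img[cbind(i, j)]; b <- img[cbind(i, j + 1)]
  cc <- img[cbind(i + 1, j)]; d <- img[cbind(i + 1, j + 1)]
  out[ok] <- (1 - dv[ok]) * ((1 - du[ok]) * a + du[ok] * b) +
    dv[ok] * ((1 - du[ok]) * cc + du[ok] * d)
  out
}

#' Rectify a stereo image pair
#'
#' Rotates both cameras onto a common image plane whose x-axis is the
#' baseline, so that corresponding points share an image row, and warps
#' the two images accordingly (inverse mapping with bilinear
#' interpolation). The returned rig is in the parallel configuration.
#'
#' @param left,right grayscale image matrices (values in \[0,1\]).
#' @param rig the calibrated [StereoRig-class] of the input pair.
#' @return List with `left`, `right` (rectified images, same size),
#'   `rig` (rectified rig), and the 3x3 pixel homographies `Hl`, `Hr`
#'   mapping original to rectified pixel coordinates.
#' @export
rectifyPair <- function(left, right, rig) {
  Rn <- rectifyingRotation(rig)
  C2 <- drop(-t(rig@R) %*% rig@T)
  b <- sqrt(sum(C2^2))
  caml <- rig@left; camr <- rig@right
  if (length(caml@dist) || length(camr@dist))
    stop("rectifyPair expects undistorted images (empty distortion)")
  K <- matrix(c(caml@fx, 0, 0, 0, caml@fy, 0, caml@cx, caml@cy, 1), 3, 3)
  Kl <- matrix(c(caml@fx, 0, 0, 0, caml@fy, 0, caml@cx, caml@cy, 1), 3, 3)
  Kr <- matrix(c(camr@fx, 0, 0, 0, camr@fy, 0, camr@cx, camr@cy, 1), 3, 3)
  # homographies old-pixels -> new-pixels: x_new = K Rn Rcam^-1 Kcam^-1 x_old
  Hl <- K %*% Rn %*% solve(Kl)
  Hr <- K %*% Rn %*% t(rig@R) %*% solve(Kr)
  warp <- function(img, H) {
    Hi <- solve(H)
    Wd <- ncol(img); Hh <- nrow(img)
    g <- expand.grid(u = 0:(Wd - 1), v = 0:(Hh - 1))
    p <- cbind(g$u, g$v, 1) %*% t(Hi)
    u <- p[, 1] / p[, 3]; v <- p[, 2] / p[, 3]
    out <- bilinearSample(img, u, v)
    out[is.na(out)] <- 0
    matrix(out, Hh, Wd, byrow = TRUE)
  }
  newRig <- stereoRig(left = rig@left, right = rig@right, baseline = b,
                      R = diag(3), T = c(-b, 0, 0),
                      workingRange = rig@workingRange)
  list(left = warp(left, Hl), right = warp(right, Hr), rig = newRig,
       Hl = Hl, Hr = Hr)
}

#' Dense disparity by normalized cross-correlation
#'
#' Block matching along rectified rows: for each pixel of the left image
#' the disparity maximizing the windowed NCC is selected and refined to
#' sub-pixel precision with a 3-point parabola fit over the correlation
#' peak. Low-texture windows and peaks below `thresh` are masked invalid.
#'
#' @param left,right rectified grayscale matrices.
#' @param window odd window size in pixels (default 11).
#' @param searchRange integer vector `c(dmin, dmax)` of disparities to
#'   scan (pixels).
#' @param thresh NCC acceptance threshold (default 0.7).
#' @return List with `disparity` (matrix, NA = invalid) and `valid`
#'   (logical matrix).
#' @export
disparityNCC <- function(left, right, window = 11L,
                         searchRange = c(0L, 64L), thresh = 0.7) {
  if (window %% 2 == 0) stop("window must be odd")
  if (diff(searchRange) >= ncol(left))
    stop("search range exceeds image width")
  d <- ncc_disparity_cpp(left, right, as.integer(window),
                         as.integer(searchRange[1]),
                         as.integer(searchRange[2]), thresh)
  list(disparity = d, valid = !is.na(d))
}

#' Intersect rays with a plane
#'
#' Solves `(o + t dir) . n0 - d0 = 0` for each ray.
#'
#' @param origin length-3 ray origin or N x 3 matrix.
#' @param dir length-3 direction or N x 3 matrix.
#' @param plane a [Plane-class].
#' @return N x 3 matrix of intersection points.
#' @export
rayPlaneIntersect <- function(origin, dir, plane) {
  if (is.null(dim(dir))) dir <- matrix(dir, 1, 3)
  if (is.null(dim(origin))) origin <- matrix(origin, nrow(dir), 3, byrow = TRUE)
  dn <- drop(dir %*% plane@n0)
  if (any(abs(dn) < 1e-9)) stop("ray parallel to plane: no intersection")
  t <- (plane@d0 - drop(origin %*% plane@n0)) / dn
  origin + dir * t
}

# RQ decomposition of a 3x3 matrix into upper-triangular K (positive
# diagonal) and rotation R
rq3 <- function(M) {
  P <- matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3, 3)
  qrres <- qr(t(P %*% M))
  Q <- qr.Q(qrres); Rr <- qr.R(qrres)
  K <- P %*% t(Rr) %*% P
  R <- P %*% t(Q)
  s <- sign(diag(K)); s[s == 0] <- 1
  S <- diag(s)
  list(K = K %*% S, R = S %*% R)
}

#' Calibrate a projector from 3D-pixel correspondences
#'
#' Estimates projector intrinsics and pose from correspondences between
#' 3D points (reference camera frame, typically obtained by ray-plane
#' intersection of projected checkerboard corners with a calibration
#' plane) and the projector pixels that generated them. A direct linear
#' transform initializes the 3x4 projection matrix, which is decomposed
#' into intrinsics and pose and refined by minimizing the re-projection
#' error.
#'
#' @param points3d N x 3 matrix of 3D points (mm), aggregated over views.
#' @param pixels N x 2 matrix of corresponding projector pixels.
#' @param width,height projector image size in pixels.
#' @param refine logical; run the nonlinear refinement (default TRUE).
#' @return A [ProjectorModel-class] with attributes `rms` (re-projection
#'   RMS error, pixels) and `residuals`.
#' @export
calibrateProjector <- function(points3d, pixels, width, height,
                               refine = TRUE) {
  n <- nrow(points3d)
  if (n < 6) stop("need at least 6 correspondences")
  # rank check: points must not be coplanar-degenerate for DLT
  cen <- colMeans(points3d)
  sv <- svd(sweep(points3d, 2, cen))$d
  if (sv[3] < 1e-6 * sv[1])
    stop("rank deficiency: correspondences are coplanar; use several plane poses")
  # DLT with normalization
  s3 <- sqrt(3) / mean(sqrt(rowSums(sweep(points3d, 2, cen)^2)))
  cen2 <- colMeans(pixels)
  s2 <- sqrt(2) / mean(sqrt(rowSums(sweep(pixels, 2, cen2)^2)))
  Xn <- sweep(points3d, 2, cen) * s3
  xn <- sweep(pixels, 2, cen2) * s2
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    X <- c(Xn[i, ], 1)
    A[2 * i - 1, ] <- c(X, rep(0, 4), -xn[i, 1] * X)
    A[2 * i, ] <- c(rep(0, 4), X, -xn[i, 2] * X)
  }
  p <- svd(A)$v[, 12]
  P <- matrix(p, 3, 4, byrow = TRUE)
  T3 <- rbind(cbind(diag(3) * s3, -s3 * cen), c(0, 0, 0, 1))
  T2 <- rbind(c(s2, 0, -s2 * cen2[1]), c(0, s2, -s2 * cen2[2]), c(0, 0, 1))
  P <- solve(T2) %*% P %*% T3
  # enforce the convention that points project with positive depth
  X1 <- c(points3d[1, ], 1)
  if ((P %*% X1)[3] < 0) P <- -P
  M <- P[, 1:3]
  dec <- rq3(M)
  K <- dec$K / dec$K[3, 3]
  R <- dec$R
  if (det(R) < 0) {
    P <- -P
    dec <- rq3(P[, 1:3])
    K <- dec$K / dec$K[3, 3]
    R <- dec$R
  }
  Tv <- drop(solve(dec$K, P[, 4]))
  par0 <- c(fx = K[1, 1], fy = K[2, 2], cx = K[1, 3], cy = K[2, 3],
            rodriguesFromR(R), Tv)
  reproj <- function(par) {
    Rm <- rodriguesToR(par[5:7])
    cam <- new("PinholeCamera", fx = par[1], fy = par[2],
               cx = min(max(par[3], 0), width - 1),
               cy = min(max(par[4], 0), height - 1),
               width = width, height = height, dist = numeric(0))
    pts <- sweep(points3d %*% t(Rm), 2, par[8:10], "+")
    projectPoint(cam, pts)
  }
  objective <- function(par) {
    pr <- try(reproj(par), silent = TRUE)
    if (inherits(pr, "try-error")) return(1e12)
    sum((pr - pixels)^2)
  }
  par <- par0
  if (refine) {
    opt <- optim(par0, objective, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    if (opt$value < objective(par0)) par <- opt$par
  }
  pr <- reproj(par)
  res <- sqrt(rowSums((pr - pixels)^2))
  cam <- pinholeCamera(fx = par[[1]], fy = par[[2]], cx = par[[3]],
                       cy = par[[4]], width = width, height = height)
  model <- projectorModel(cam, R = rodriguesToR(par[5:7]), T = par[8:10])
  attr(model, "rms") <- sqrt(mean(res^2))
  attr(model, "residuals") <- res
  model
}

# axis-angle (Rodrigues) vector from a rotation matrix and back
rodriguesFromR <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  th <- acos(pmin(1, pmax(-1, ct)))
  if (th < 1e-12) return(c(0, 0, 0))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (abs(sin(th)) < 1e-8) {
    # th ~ pi: extract axis from R + I
    B <- (R + diag(3)) / 2
    a <- sqrt(pmax(diag(B), 0))
    i <- which.max(a)
    a <- B[, i] / a[i]
    return(a / sqrt(sum(a^2)) * th)
  }
  w / (2 * sin(th)) * th
}

rodriguesToR <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  rotationMatrix(v / th, th * 180 / pi)
}

#' Read a calibration configuration file
#'
#' Reads a YAML or JSON file with camera fields `fx, fy, cx, cy, width,
#' height, dist` for `left` and `right`, plus `R` (row-major 3x3), `T`,
#' `baseline_mm` and optional `working_range_mm` and `projector`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A [StereoRig-class]; when a projector section is present, the
#'   [ProjectorModel-class] is attached as attribute `projector`.
#' @export
readCalibration <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  mkcam <- function(x) pinholeCamera(
    fx = x$fx, fy = x$fy %||% x$fx, cx = x$cx, cy = x$cy,
    width = x$width, height = x$height,
    dist = as.numeric(x$dist %||% numeric(0)))
  R <- matrix(as.numeric(unlist(cfg$R %||% diag(3))), 3, 3, byrow = TRUE)
  rig <- stereoRig(left = mkcam(cfg$left), right = mkcam(cfg$right),
                   baseline = cfg$baseline_mm,
                   R = R, T = as.numeric(cfg$T %||% c(-cfg$baseline_mm, 0, 0)),
                   workingRange = as.numeric(cfg$working_range_mm %||% c(150, 350)))
  if (!is.null(cfg$projector)) {
    p <- cfg$projector
    Rp <- matrix(as.numeric(unlist(p$R %||% diag(3))), 3, 3, byrow = TRUE)
    attr(rig, "projector") <- projectorModel(mkcam(p), R = Rp,
                                             T = as.numeric(p$T %||% c(0, 0, 0)))
  }
  rig
}
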