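#' Triangulate marker fiducials from a stereo pair
#'
#' Lifts corresponding fiducial detections in the left and right
#' (rectified) images to 3D by disparity triangulation, preserving the
#' fiducial ordering so visits can be matched point-to-point.
#'
#' @param pixLeft,pixRight N x 2 matrices of fiducial pixels, same order.
#' @param rig rectified [StereoRig-class].
#' @return N x 3 matrix of fiducial positions (mm, left camera frame).
#' @export
triangulateFiducials <- function(pixLeft, pixRight, rig) {
  if (nrow(pixLeft) != nrow(pixRight)) stop("fiducial counts differ")
  if (nrow(pixLeft) < 3) stop("registration impossible: need >= 3 fiducials")
  disp <- pixLeft[, 1] - pixRight[, 1]
  pts <- triangulateRectified(rig, pixLeft, disp)
  # non-collinearity check
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300))
    stop("registration impossible: fiducials are collinear")
  pts
}

#' Least-squares rigid alignment of two point sets
#'
#' SVD-based (Arun) solution of `p_curr ~ R p_prev + T` minimizing the
#' sum of squared residuals; a reflection in the SVD solution is
#' corrected so the returned rotation is proper (`det(R) = +1`).
#'
#' @param pPrev,pCurr N x 3 matrices of corresponding points (N >= 3,
#'   non-collinear).
#' @return A [RigidTransform-class]; attribute `rms` is the RMS residual
#'   after alignment (mm).
#' @export
rigidLsq <- function(pPrev, pCurr) {
  if (nrow(pPrev) != nrow(pCurr)) stop("point counts differ")
  if (nrow(pPrev) < 3) stop("need at least 3 correspondences")
  cp <- colMeans(pPrev); cq <- colMeans(pCurr)
  A <- sweep(pPrev, 2, cp); B <- sweep(pCurr, 2, cq)
  sv <- svd(A)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300)) stop("degenerate: collinear points")
  H <- t(A) %*% B
  dec <- svd(H)
  D <- diag(c(1, 1, sign(det(dec$v %*% t(dec$u)))))
  R <- dec$v %*% D %*% t(dec$u)
  T <- cq - drop(R %*% cp)
  tf <- rigidTransform(R, T)
  attr(tf, "rms") <- sqrt(mean(rowSums((applyTransform(tf, pPrev) - pCurr)^2)))
  tf
}

#' Render the projector overlay image
#'
#' Transforms AR content points (previous-visit perimeter or classified
#' surface points, in the current reference-camera frame) into the
#' projector frame, projects them through the projector pinhole, and
#' rasterizes them as a polyline or as point splats. Points behind the
#' projector or outside its frustum produce no pixels.
#'
#' @param points N x 3 matrix (mm, reference camera frame).
#' @param projector [ProjectorModel-class].
#' @param style `"polyline"` (closed contour, Bresenham segments) or
#'   `"points"` (disc splats).
#' @param radius splat radius in pixels for `style = "points"`.
#' @return Logical matrix at projector resolution (TRUE = lit);
#'   attribute `projected` holds the N x 2 projected pixels (NA when
#'   clipped).
#' @export
renderProjectorOverlay <- function(points, projector,
                                   style = c("polyline", "points"),
                                   radius = 1) {
  style <- match.arg(style)
  cam <- projector@intrinsics
  W <- cam@width; H <- cam@height
  img <- matrix(FALSE, H, W)
  pp <- sweep(points %*% t(projector@R), 2, projector@T, "+")
  vis <- pp[, 3] > 0
  pix <- matrix(NA_real_, nrow(points), 2)
  if (any(vis)) pix[vis, ] <- projectPoint(cam, pp[vis, , drop = FALSE])
  inb <- vis & pix[, 1] >= 0 & pix[, 1] <= W - 1 &
    pix[, 2] >= 0 & pix[, 2] <= H - 1
  if (!any(vis)) warning("empty overlay: all points behind the projector")
  lit <- function(u, v) {
    ok <- u >= 0 & u <= W - 1 & v >= 0 & v <= H - 1
    img[cbind(round(v[ok]) + 1, round(u[ok]) + 1)] <<- TRUE
  }
  if (style == "points") {
    if (radius <= 1) lit(pix[inb, 1], pix[inb, 2])
    else {
      off <- expand.grid(du = -radius:radius, dv = -radius:radius)
      off <- off[off$du^2 + off$dv^2 <= radius^2, ]
      for (k in seq_len(nrow(off)))
        lit(pix[inb, 1] + off$du[k], pix[inb, 2] + off$dv[k])
    }
  } else {
    idx <- which(inb)
    n <- nrow(pix)
    for (k in seq_along(idx)) {
      i <- idx[k]
      j <- if (i == n) 1L else i + 1L
      if (!inb[j]) next
      p1 <- pix[i, ]; p2 <- pix[j, ]
      steps <- max(2, ceiling(max(abs(p2 - p1))) + 1)
      u <- seq(p1[1], p2[1], length.out = steps)
      v <- seq(p1[2], p2[2], length.out = steps)
      lit(u, v)
    }
  }
  attr(img, "projected") <- pix
  img
}

#' Checkerboard marker fiducials
#'
#' Inner-corner grid of the registration marker (a small adhesive
#' checkerboard placed near the wound), laid out on the skin plane. The
#' asymmetric footprint (width != height) disambiguates the marker
#' orientation between visits.
#'
#' @param center length-3 marker centre (mm).
#' @param widthMm,heightMm marker footprint (default 12 x 8 mm).
#' @param rows,cols inner-corner grid (default 2 x 3).
#' @param e1,e2 in-plane unit vectors of the marker axes.
#' @return N x 3 matrix of fiducial positions, fixed ordering.
#' @export
markerFiducials <- function(center, widthMm = 12, heightMm = 8,
                            rows = 2L, cols = 3L,
                            e1 = c(1, 0, 0), e2 = c(0, 1, 0)) {
  us <- seq(-widthMm / 2, widthMm / 2, length.out = cols + 2)[2:(cols + 1)]
  vs <- seq(-heightMm / 2, heightMm / 2, length.out = rows + 2)[2:(rows + 1)]
  g <- expand.grid(u = us, v = vs)
  sweep(outer(g$u, e1) + outer(g$v, e2), 2, center, "+")
}

#' Compare a previous visit with the current scene
#'
#' The full inter-visit AR chain: triangulate the marker fiducials in
#' both visits, solve the rigid least-squares registration
#' `p_curr ~ R p_prev + T`, map the previous visit's perimeter (and
#' optionally classified points) into the current frame, and synthesize
#' the projector overlay.
#'
#' @param prevFidL,prevFidR,currFidL,currFidR N x 2 fiducial pixel
#'   matrices for the previous/current left/right images (same marker,
#'   same ordering).
#' @param prevPerimeter M x 3 matrix: previous wound perimeter in the
#'   previous visit's camera frame.
#' @param rig rectified [StereoRig-class].
#' @param projector [ProjectorModel-class].
#' @param style overlay style, see [renderProjectorOverlay()].
#' @return List with `overlay` (projector image), `registered`
#'   (perimeter mapped to the current frame), `transform`
#'   ([RigidTransform-class]) and `rms` (fiducial residual, mm).
#' @export
arCompare <- function(prevFidL, prevFidR, currFidL, currFidR,
                      prevPerimeter, rig, projector,
                      style = "polyline") {
  if (nrow(prevFidL) != nrow(currFidL))
    stop("marker mismatch between visits")
  fPrev <- triangulateFiducials(prevFidL, prevFidR, rig)
  fCurr <- triangulateFiducials(currFidL, currFidR, rig)
  tf <- rigidLsq(fPrev, fCurr)
  reg <- applyTransform(tf, prevPerimeter)
  overlay <- renderProjectorOverlay(reg, projector, style = style)
  list(overlay = overlay, registered = reg, transform = tf,
       rms = attr(tf, "rms"))
}
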