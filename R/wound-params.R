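#' Fit the skin reference plane
#'
#' Total-least-squares plane through the skin points: the normal is the
#' smallest principal component of the centred points, oriented towards
#' the camera (negative z, since the camera looks down +z), and
#' `d0 = centroid . n0` (Hessian normal form).
#'
#' @param points N x 3 matrix of skin points (mm).
#' @return A [Plane-class]; attribute `rms` holds the RMS residual.
#' @export
fitSkinPlane <- function(points) {
  if (nrow(points) < 3) stop("need at least 3 points")
  pca <- prcomp(points, center = TRUE)
  if (pca$sdev[2] < 1e-9 * max(pca$sdev[1], 1e-300))
    stop("rank error: points are collinear")
  n0 <- pca$rotation[, 3]
  if (n0[3] > 0) n0 <- -n0
  pl <- plane3d(n0, sum(colMeans(points) * n0))
  attr(pl, "rms") <- sqrt(mean(planeDistance(pl, points)^2))
  pl
}

# orient a plane so that the given points have non-negative median signed
# distance (wound interior positive)
orientPlaneTowards <- function(plane, points) {
  s <- planeDistance(plane, points)
  if (median(s) < 0) plane3d(-plane@n0, -plane@d0) else plane
}

#' Maximal wound depth
#'
#' Distance between the skin plane and the farthest mesh point:
#' `sup over mesh vertices x of (n0 . x - d0)`, clamped at 0 when the
#' whole mesh lies above the plane.
#'
#' @param mesh wound [QuadMesh-class].
#' @param plane the skin [Plane-class].
#' @param orient `"auto"` flips the plane so the wound interior has
#'   positive signed distance; `"asis"` trusts the given orientation.
#' @return Depth in mm.
#' @export
woundDepth <- function(mesh, plane, orient = c("auto", "asis")) {
  orient <- match.arg(orient)
  V <- meshVertices(mesh)
  if (orient == "auto") plane <- orientPlaneTowards(plane, V)
  max(0, max(planeDistance(plane, V)))
}

#' Trace the wound boundary in the 2D image
#'
#' Moore-neighbour contour tracing with Jacob's stopping criterion: the
#' walk terminates when the start pixel is re-entered from its original
#' entry direction, which closes the 8-connected boundary exactly once.
#' If the mask has several components the largest is traced (warning).
#'
#' @param mask logical wound mask.
#' @return M x 2 matrix of ordered boundary pixels `(x, y)`, 0-based;
#'   closed (last pixel is an 8-neighbour of the first).
#' @export
tracePerimeter2d <- function(mask) {
  if (!any(mask)) stop("empty mask")
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab > 1) {
    warning("mask has multiple components; tracing the largest")
    sizes <- tabulate(as.vector(lab[lab > 0]), nbins = nlab)
    mask <- as.matrix(lab == which.max(sizes))
  }
  H <- nrow(mask); W <- ncol(mask)
  inside <- function(x, y) x >= 0 && x < W && y >= 0 && y < H && mask[y + 1, x + 1]
  # start: first wound pixel in raster order (top-to-bottom, left-to-right)
  idx <- which(t(mask))[1]   # t() so raster order is row by row
  x0 <- (idx - 1) %% W; y0 <- (idx - 1) %/% W
  if (sum(mask) == 1) return(cbind(x = x0, y = y0))
  # Moore neighbourhood, scanned rotationally starting west
  nb <- cbind(x = c(-1, -1, 0, 1, 1, 1, 0, -1),
              y = c(0, -1, -1, -1, 0, 1, 1, 1))
  out <- matrix(NA_integer_, sum(mask) * 4 + 8, 2)
  np <- 0L
  cx <- x0; cy <- y0
  backtrack <- 2L   # entered from the west during the raster scan
  sx2 <- NA_integer_; sy2 <- NA_integer_
  repeat {
    nxty <- NULL
    for (k in 0:7) {
      dir <- ((backtrack - 1 + k) %% 8) + 1
      nx <- cx + nb[dir, 1]; ny <- cy + nb[dir, 2]
      if (inside(nx, ny)) { nxty <- c(nx, ny, dir); break }
    }
    if (is.null(nxty)) return(cbind(x = x0, y = y0))  # isolated pixel
    nx <- nxty[1]; ny <- nxty[2]; dir <- nxty[3]
    # Jacob's stopping criterion: the walk re-enters the start pixel and
    # repeats the original first move
    if (np > 0L && cx == x0 && cy == y0 && nx == sx2 && ny == sy2) break
    if (np == 0L) { sx2 <- nx; sy2 <- ny }
    np <- np + 1L
    if (np > nrow(out)) out <- rbind(out, out)
    out[np, ] <- c(cx, cy)
    prevDir <- ((dir + 4 - 1) %% 8) + 1   # direction back to (cx, cy)
    backtrack <- (prevDir %% 8) + 1
    cx <- nx; cy <- ny
    if (np > 8L * sum(mask)) stop("boundary tracing failed to terminate")
  }
  out[seq_len(np), , drop = FALSE]
}

#' 3D perimeter from traced boundary pixels
#'
#' Lifts the ordered boundary pixels to 3D through the pixel map
#' (invalid pixels are skipped and bridged), applies a short circular
#' moving average to suppress the 8-connected staircase, sub-samples the
#' polygon to chords of a few sample spacings, and sums the Euclidean
#' distances of contiguous points including the closing segment. With
#' `correction = TRUE` (default) the half-pixel digitization offset is
#' compensated by adding `pi * pitch` (the length increase of the
#' outward half-pitch normal offset of a closed curve).
#'
#' @param boundary M x 2 matrix of ordered boundary pixels from
#'   [tracePerimeter2d()].
#' @param pixelMap,points pixel provenance map and 3D points (or a
#'   [WoundCloud-class] passed as `pixelMap`).
#' @param smoothWindow circular moving-average window for the in-plane
#'   coordinates (odd, default 3; kept short to preserve corners).
#' @param normalWindow moving-average window for the component along the
#'   boundary-plane normal, where reconstruction noise concentrates
#'   (default 7).
#' @param chordStep sub-sampling step in boundary samples (default 2).
#' @param correction apply the half-pitch digitization correction.
#' @return Perimeter in mm.
#' @export
perimeter3d <- function(boundary, pixelMap, points = NULL, smoothWindow = 3L,
                        normalWindow = 7L, chordStep = 2L, correction = TRUE) {
  if (is(pixelMap, "WoundCloud")) {
    points <- pixelMap@points; pixelMap <- pixelMap@pixelMap
  }
  P <- liftBoundary3d(boundary, pixelMap, points, smoothWindow, normalWindow)
  n <- nrow(P)
  pitch <- attr(P, "pitch")
  if (chordStep > 1 && n > 3 * chordStep)
    P <- P[seq(1, n, by = chordStep), , drop = FALSE]
  seg <- rbind(diff(P), P[1, ] - P[nrow(P), ])
  per <- sum(sqrt(rowSums(seg^2)))
  if (correction) per <- per + pi * pitch
  per
}

#' Perimeter of the wound opening
#'
#' Length of the rim anchor polygon (see [rimAnchorPolygon()]) after
#' orthogonal projection onto the skin plane: the perimeter of the wound
#' opening at skin level, which is the clinically reported quantity and
#' is insensitive to whether the traced pixels lie at the bottom of a
#' steep wall.
#'
#' @param anchors ordered closed M x 3 rim polygon.
#' @param plane skin [Plane-class].
#' @param chordStep sub-sampling step (samples, default 2) suppressing
#'   the residual pixel staircase.
#' @return Perimeter in mm.
#' @export
rimPerimeter <- function(anchors, plane, chordStep = 2L) {
  uv <- anchors %*% planeBasis(plane)
  n <- nrow(uv)
  if (chordStep > 1 && n > 3 * chordStep)
    uv <- uv[seq(1, n, by = chordStep), , drop = FALSE]
  seg <- rbind(diff(uv), uv[1, ] - uv[nrow(uv), ])
  sum(sqrt(rowSums(seg^2)))
}

#' Lift traced boundary pixels to a smoothed 3D polygon
#'
#' Maps ordered boundary pixels through the pixel provenance map (invalid
#' pixels skipped and bridged) and applies circular moving-average
#' smoothing: a short window in the boundary plane (preserving corners)
#' and a longer one along the plane normal, where reconstruction noise
#' and steep-wall quantization concentrate.
#'
#' @param boundary M x 2 ordered boundary pixels ([tracePerimeter2d()]).
#' @param pixelMap,points provenance map and 3D points.
#' @param smoothWindow,normalWindow smoothing windows (samples).
#' @return Ordered closed N x 3 polygon; attribute `pitch` is the median
#'   spacing of the raw lifted points.
#' @export
liftBoundary3d <- function(boundary, pixelMap, points, smoothWindow = 3L,
                           normalWindow = 7L) {
  idx <- pixelMap[cbind(boundary[, 2] + 1, boundary[, 1] + 1)]
  idx <- idx[!is.na(idx)]
  if (length(idx) < 3) stop("fewer than 3 valid 3D boundary points")
  P <- points[idx, , drop = FALSE]
  n <- nrow(P)
  pitch <- medianSpacing(P)
  circSmooth <- function(v, w) {
    if (w <= 1 || n <= w) return(v)
    h <- (w - 1) %/% 2
    ext <- c(v[(n - h + 1):n], v, v[1:h])
    stats::filter(ext, rep(1 / w, w), sides = 2)[(h + 1):(h + n)]
  }
  if (n > max(smoothWindow, normalWindow)) {
    pca <- prcomp(P, center = TRUE)
    Q <- pca$x
    Q[, 1] <- circSmooth(Q[, 1], smoothWindow)
    Q[, 2] <- circSmooth(Q[, 2], smoothWindow)
    Q[, 3] <- circSmooth(Q[, 3], normalWindow)
    P <- sweep(Q %*% t(pca$rotation), 2, pca$center, "+")
  }
  attr(P, "pitch") <- pitch
  P
}

#' 3D surface area of the wound mesh
#'
#' Total area of the mesh quadrilaterals via the cross-product rule: for
#' each quad, half the sum of the cross-product magnitudes of the two
#' grid edge vectors taken at two opposite corners.
#'
#' @param mesh wound [QuadMesh-class].
#' @return Area in mm^2.
#' @export
area3d <- function(mesh) {
  V <- mesh@vertices
  r <- dim(V)[1]; c <- dim(V)[2]
  i <- seq_len(r - 1); j <- seq_len(c - 1)
  A <- V[i, j, , drop = FALSE]
  B <- V[i + 1, j, , drop = FALSE]
  C <- V[i, j + 1, , drop = FALSE]
  D <- V[i + 1, j + 1, , drop = FALSE]
  crossNorm <- function(U, W) {
    cx <- U[, , 2] * W[, , 3] - U[, , 3] * W[, , 2]
    cy <- U[, , 3] * W[, , 1] - U[, , 1] * W[, , 3]
    cz <- U[, , 1] * W[, , 2] - U[, , 2] * W[, , 1]
    sqrt(cx^2 + cy^2 + cz^2)
  }
  n1 <- crossNorm(B - A, C - A)         # at corner (r, c)
  n2 <- crossNorm(D - B, D - C)         # at corner (r+1, c+1)
  sum((n1 + n2) / 2)
}

# in-plane orthonormal basis (e1, e2) completing the plane normal
planeBasis <- function(plane) {
  n <- plane@n0
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  cbind(e1, e2)
}

# project points onto the plane coordinates (2D, mm)
projectToPlane <- function(points, plane) {
  B <- planeBasis(plane)
  sweep(points, 2, colMeans(points)) %*% B
}

#' 2D alpha-shape of a planar point set
#'
#' Delaunay-based alpha shape: triangles whose circumradius exceeds
#' `alpha` are discarded; the remaining union is the alpha complex. When
#' the requested alpha would orphan points (the boundary must enclose
#' all points), alpha is grown to the smallest value whose complex
#' covers every point, with a warning.
#'
#' @param uv N x 2 matrix of planar points.
#' @param alpha radius parameter (same units as `uv`); `NULL` defaults
#'   to twice the median nearest-neighbour spacing.
#' @return List with `area` (union of kept triangles, holes excluded),
#'   `triangles` (index matrix), `boundaryLength`, `boundaryEdges`
#'   (kept-complex edges used once), and the `alpha` actually used.
#' @export
alphaShape2d <- function(uv, alpha = NULL) {
  n <- nrow(uv)
  if (n < 3) stop("need at least 3 points")
  pitch <- medianSpacing(uv)
  if (is.null(alpha)) alpha <- 2 * pitch
  # centre/scale and deterministically jitter to break grid co-circularity
  ctr <- colMeans(uv); sc <- max(apply(uv, 2, function(v) diff(range(v))), 1e-12)
  w <- sweep(uv, 2, ctr) / sc
  set0 <- (seq_len(n) * 2654435761) %% 100003L
  jit <- cbind(set0, (set0 * 31L) %% 100019L) / 1e5
  w <- w + (jit - 0.5) * 1e-6
  ordIdx <- order(round(w[, 1] * 64), w[, 2])
  tri <- delaunay_cpp(w[ordIdx, 1], w[ordIdx, 2])
  tri <- matrix(ordIdx[tri], ncol = 3)
  p1 <- uv[tri[, 1], , drop = FALSE]
  p2 <- uv[tri[, 2], , drop = FALSE]
  p3 <- uv[tri[, 3], , drop = FALSE]
  a <- sqrt(rowSums((p2 - p3)^2))
  b <- sqrt(rowSums((p1 - p3)^2))
  cc <- sqrt(rowSums((p1 - p2)^2))
  areaT <- 0.5 * abs((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
                     (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
  circ <- a * b * cc / (4 * pmax(areaT, 1e-300))
  # smallest alpha that leaves no point uncovered
  minCirc <- rep(Inf, n)
  for (k in 1:3) {
    ag <- tapply(circ, tri[, k], min)
    ii <- as.integer(names(ag))
    minCirc[ii] <- pmin(minCirc[ii], ag)
  }
  needed <- max(minCirc[is.finite(minCirc)])
  if (needed > alpha) {
    warning(sprintf("alpha grown from %.3g to %.3g to enclose all points",
                    alpha, needed))
    alpha <- needed
  }
  keep <- circ <= alpha + 1e-12
  triK <- tri[keep, , drop = FALSE]
  edges <- rbind(triK[, c(1, 2)], triK[, c(2, 3)], triK[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  tab <- table(key)
  bkey <- names(tab)[tab == 1]
  be <- do.call(rbind, strsplit(bkey, " "))
  be <- matrix(as.integer(be), ncol = 2)
  blen <- sum(sqrt(rowSums((uv[be[, 1], , drop = FALSE] -
                            uv[be[, 2], , drop = FALSE])^2)))
  list(area = sum(areaT[keep]), triangles = triK, boundaryLength = blen,
       boundaryEdges = be, alpha = alpha)
}

#' Projected (footprint) area of the wound
#'
#' Rotates the wound points so the skin plane is parallel to the x-y
#' plane, drops the normal coordinate, and measures the area of the 2D
#' alpha-shape enclosing all projected points — the contactless
#' equivalent of acetate tracing. With `correction = TRUE` (default) the
#' half-pitch digitization band `boundaryLength * pitch / 2` is added to
#' compensate pixel-centre sampling.
#'
#' @param points wound points (N x 3) or a [WoundCloud-class] (wound
#'   label used).
#' @param plane skin [Plane-class].
#' @param alpha alpha radius (mm); `NULL` = twice the median spacing.
#' @param correction apply the half-pitch boundary band correction.
#' @return Area in mm^2; attributes `alpha` and `boundaryLength`.
#' @export
projectedArea <- function(points, plane, alpha = NULL, correction = TRUE) {
  if (is(points, "WoundCloud")) points <- cloudPoints(points, "wound")
  if (nrow(points) < 3) stop("need at least 3 points")
  uv <- projectToPlane(points, plane)
  as2 <- alphaShape2d(uv, alpha)
  area <- as2$area
  if (correction) {
    pitch <- medianSpacing(uv)
    area <- area + 0.5 * pitch * as2$boundaryLength
  }
  attr(area, "alpha") <- as2$alpha
  attr(area, "boundaryLength") <- as2$boundaryLength
  area
}

#' Main axes of the wound footprint
#'
#' Principal component analysis of the plane-projected points: the first
#' principal direction maximizes the variance of the projections, the
#' second is orthogonal to it; the axis lengths are the extents
#' (max - min) of the projections along the two directions, so the axes
#' span the wound. With `correction = TRUE` one sampling pitch is added
#' to each extent (half a sample cell per side).
#'
#' @param points wound points (N x 3) or [WoundCloud-class].
#' @param plane skin [Plane-class].
#' @param correction add one sampling pitch to each extent.
#' @return List with `major`, `minor` (mm) and `directions` (3D unit
#'   vectors, columns).
#' @export
mainAxes <- function(points, plane, correction = TRUE) {
  if (is(points, "WoundCloud")) points <- cloudPoints(points, "wound")
  if (nrow(points) < 2) stop("need at least 2 points")
  uv <- projectToPlane(points, plane)
  if (max(apply(uv, 2, stats::var)) < 1e-18) stop("zero-variance cloud")
  pca <- prcomp(uv, center = TRUE)
  ext <- apply(pca$x, 2, function(v) diff(range(v)))
  if (correction) ext <- ext + medianSpacing(uv)
  ord <- order(ext, decreasing = TRUE)
  B <- planeBasis(plane)
  dirs <- unname(B %*% pca$rotation[, ord])
  list(major = unname(ext[ord[1]]), minor = unname(ext[ord[2]]),
       directions = dirs)
}

#' Wound cavity volume
#'
#' Measures the region enclosed between the wound mesh and the skin
#' plane. The plane acts as the constraint that keeps the boundary
#' surface from collapsing into the cavity: mesh vertices above the
#' plane are clamped onto it and the cavity is closed by the orthogonal
#' projection of the mesh onto the plane (the cap). The enclosed volume
#' is integrated exactly for the piecewise-linear surface by the prism
#' rule in the plane frame (signed projected triangle area times mean
#' depth), which is insensitive to the scene's absolute position.
#'
#' @param mesh wound [QuadMesh-class].
#' @param plane skin [Plane-class].
#' @param orient as in [woundDepth()].
#' @return Volume in mm^3 (0 for a flat wound).
#' @export
woundVolume <- function(mesh, plane, orient = c("auto", "asis")) {
  orient <- match.arg(orient)
  V <- meshVertices(mesh)
  if (orient == "auto") plane <- orientPlaneTowards(plane, V)
  # plane frame: (u, v) in-plane, w = signed distance (cavity positive);
  # vertices above the plane are clamped onto it (the plane constraint)
  B <- planeBasis(plane)
  uv <- V %*% B
  w <- pmax(0, planeDistance(plane, V))
  faces <- meshTriangles(mesh)$faces
  u1 <- uv[faces[, 1], 1]; v1 <- uv[faces[, 1], 2]
  u2 <- uv[faces[, 2], 1]; v2 <- uv[faces[, 2], 2]
  u3 <- uv[faces[, 3], 1]; v3 <- uv[faces[, 3], 2]
  signedA <- 0.5 * ((u2 - u1) * (v3 - v1) - (u3 - u1) * (v2 - v1))
  wm <- (w[faces[, 1]] + w[faces[, 2]] + w[faces[, 3]]) / 3
  # prism rule: exact volume of the region between the piecewise-linear
  # mesh surface and its orthogonal projection (the cap) on the plane
  abs(sum(signedA * wm))
}

# indices (into the column-major vertex matrix) of the grid rim, ordered
rimIndices <- function(r, c) {
  ij <- rbind(
    cbind(seq_len(r), 1),
    cbind(r, seq(2, c)),
    cbind(seq(r - 1, 1), c),
    cbind(1, seq(c - 1, 2)))
  ij[, 1] + (ij[, 2] - 1) * r
}

#' Compute the full wound report
#'
#' Runs the six clinical parameter computations on a labelled cloud and
#' its wound mesh: skin plane fit, maximal depth, perimeter (the wound
#' rim traced on the mask, lifted through the pixel map and measured at
#' the level where the wound meets the skin), mesh 3D area, projected
#' area, main axes and cavity volume; optionally appends a tissue
#' composition.
#'
#' @param cloud labelled [WoundCloud-class].
#' @param mesh wound [QuadMesh-class].
#' @param woundMask logical wound mask used for the perimeter trace.
#' @param alpha alpha radius for the projected area (mm), NULL = auto.
#' @param tissue optional named tissue fractions to embed.
#' @param meta metadata list stored in the report.
#' @param correction apply digitization corrections (see the individual
#'   parameter functions). With `correction = FALSE` the perimeter falls
#'   back to the plain boundary lift of [perimeter3d()].
#' @return A [WoundReport-class].
#' @export
computeReport <- function(cloud, mesh, woundMask, alpha = NULL,
                          tissue = numeric(0), meta = list(),
                          correction = TRUE) {
  skin <- cloudPoints(cloud, "skin")
  wound <- cloudPoints(cloud, "wound")
  plane <- fitSkinPlane(skin)
  plane <- orientPlaneTowards(plane, meshVertices(mesh))
  depth <- woundDepth(mesh, plane, orient = "asis")
  if (correction) {
    anch <- rimAnchorPolygon(woundMask, cloud@pixelMap, cloud@points,
                             plane = plane)
    per <- rimPerimeter(anch, plane)
  } else {
    bnd <- tracePerimeter2d(woundMask)
    per <- perimeter3d(bnd, cloud@pixelMap, cloud@points,
                       correction = correction)
  }
  a3 <- area3d(mesh)
  ap <- projectedArea(wound, plane, alpha = alpha, correction = correction)
  ax <- mainAxes(wound, plane, correction = correction)
  vol <- woundVolume(mesh, plane, orient = "asis")
  woundReport(depth = depth, perimeter = per, area3d = a3,
              areaProjected = as.numeric(ap),
              axisMajor = ax$major, axisMinor = ax$minor, volume = vol,
              tissue = tissue, meta = meta)
}
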