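#' Pinhole camera model
#'
#' Intrinsic model of a (possibly distorted) pinhole camera. Pixel
#' coordinates follow the imaging convention: origin at the top-left pixel
#' centre, x to the right, y down, 0-based. The camera frame is
#' right-handed with +z forward into the scene.
#'
#' @slot fx,fy focal lengths in pixels.
#' @slot cx,cy principal point in pixels.
#' @slot width,height image size in pixels.
#' @slot dist distortion coefficients `(k1, k2, k3, p1, p2)` (radial +
#'   tangential); an empty vector means an ideal pinhole.
#' @export
setClass("PinholeCamera",
  representation(fx = "numeric", fy = "numeric", cx = "numeric",
                 cy = "numeric", width = "numeric", height = "numeric",
                 dist = "numeric"),
  prototype(dist = numeric(0)))

setValidity("PinholeCamera", function(object) {
  if (object@fx <= 0 || object@fy <= 0) return("focal lengths must be > 0")
  if (object@width <= 0 || object@height <= 0) return("image size must be > 0")
  if (object@cx < 0 || object@cx > object@width - 1 ||
      object@cy < 0 || object@cy > object@height - 1)
    return("principal point must lie inside the image")
  TRUE
})

#' Construct a pinhole camera
#'
#' If `fovH`/`fovV` (degrees) are supplied they are checked for consistency
#' with the focal lengths via `f = C / (2 tan(FOV/2))` (1% tolerance,
#' distortion-free cameras only).
#'
#' @param fx,fy focal lengths (pixels); `fy` defaults to `fx`.
#' @param cx,cy principal point (pixels); default image centre.
#' @param width,height image size (pixels).
#' @param dist distortion coefficients, default none.
#' @param fovH,fovV optional nominal fields of view (degrees) to validate.
#' @return A [PinholeCamera-class] object.
#' @examples
#' cam <- pinholeCamera(fx = 1316, width = 2208, height = 1242)
#' fieldOfView(cam)
#' @export
pinholeCamera <- function(fx, fy = fx, cx = (width - 1) / 2,
                          cy = (height - 1) / 2, width, height,
                          dist = numeric(0), fovH = NULL, fovV = NULL) {
  cam <- new("PinholeCamera", fx = fx, fy = fy, cx = cx, cy = cy,
             width = width, height = height, dist = dist)
  if (length(dist) == 0) {
    chk <- function(fov, f, C, lab) {
      fexp <- C / (2 * tan(fov * pi / 360))
      if (abs(fexp - f) / f > 0.01)
        stop(sprintf("%s inconsistent with focal length: expected f=%.1f, got %.1f",
                     lab, fexp, f))
    }
    if (!is.null(fovH)) chk(fovH, fx, width, "fovH")
    if (!is.null(fovV)) chk(fovV, fy, height, "fovV")
  }
  cam
}

#' Field of view of a camera
#'
#' Horizontal and vertical fields of view (degrees) derived from the focal
#' lengths and sensor size.
#' @param camera a [PinholeCamera-class].
#' @return Named numeric vector `c(h=, v=)` in degrees.
#' @export
fieldOfView <- function(camera) {
  c(h = 2 * atan(camera@width / (2 * camera@fx)) * 180 / pi,
    v = 2 * atan(camera@height / (2 * camera@fy)) * 180 / pi)
}

setMethod("show", "PinholeCamera", function(object) {
  fov <- fieldOfView(object)
  cat(sprintf("PinholeCamera %gx%g px, f=(%.1f, %.1f) px, c=(%.1f, %.1f), FOV %.1fx%.1f deg, %d distortion coeffs\n",
              object@width, object@height, object@fx, object@fy,
              object@cx, object@cy, fov["h"], fov["v"],
              length(object@dist)))
})

#' Calibrated stereo rig
#'
#' Two pinhole cameras with a rigid relative pose. The reference frame is
#' the left camera. A point `X` in the left frame maps to the right frame
#' as `R %*% X + T`; for the parallel (rectified) configuration `R` is the
#' identity and `T = c(-baseline, 0, 0)`.
#'
#' @slot left,right the two [PinholeCamera-class] models.
#' @slot R 3x3 rotation left -> right frame.
#' @slot T translation (mm) left -> right frame.
#' @slot baseline stereo baseline (mm).
#' @slot workingRange admissible working distance range (mm).
#' @export
setClass("StereoRig",
  representation(left = "PinholeCamera", right = "PinholeCamera",
                 R = "matrix", T = "numeric", baseline = "numeric",
                 workingRange = "numeric"))

setValidity("StereoRig", function(object) {
  if (!isRotation(object@R)) return("R must be a proper rotation (det = +1)")
  if (object@baseline <= 0) return("baseline must be > 0")
  if (length(object@T) != 3) return("T must have length 3")
  TRUE
})

#' Construct a stereo rig
#'
#' @param left,right [PinholeCamera-class] models; `right` defaults to a
#'   copy of `left`.
#' @param baseline stereo baseline in mm.
#' @param R,T relative pose (left frame to right frame); default the
#'   parallel configuration `R = I`, `T = c(-baseline, 0, 0)`.
#' @param workingRange working distance range in mm.
#' @return A [StereoRig-class].
#' @export
stereoRig <- function(left, right = left, baseline,
                      R = diag(3), T = c(-baseline, 0, 0),
                      workingRange = c(150, 350)) {
  new("StereoRig", left = left, right = right, R = R, T = T,
      baseline = baseline, workingRange = workingRange)
}

setMethod("show", "StereoRig", function(object) {
  cat(sprintf("StereoRig: baseline %.1f mm, working range [%g, %g] mm\n",
              object@baseline, object@workingRange[1], object@workingRange[2]))
  cat("  left:  "); show(object@left)
  cat("  right: "); show(object@right)
})

#' Projector model
#'
#' A projector treated as an inverse pinhole camera: intrinsics plus a
#' rigid pose in the reference (left) camera frame. A point `X` in the
#' reference frame maps to projector coordinates as `R %*% X + T`.
#'
#' @slot intrinsics [PinholeCamera-class] of the projector.
#' @slot R,T rigid pose, reference camera frame to projector frame (mm).
#' @export
setClass("ProjectorModel",
  representation(intrinsics = "PinholeCamera", R = "matrix", T = "numeric"))

setValidity("ProjectorModel", function(object) {
  if (!isRotation(object@R)) return("R must be a proper rotation")
  if (length(object@T) != 3) return("T must have length 3")
  TRUE
})

#' Construct a projector model
#' @param intrinsics projector [PinholeCamera-class].
#' @param R,T pose of the reference camera frame in the projector frame.
#' @return A [ProjectorModel-class].
#' @export
projectorModel <- function(intrinsics, R = diag(3), T = c(0, 0, 0)) {
  new("ProjectorModel", intrinsics = intrinsics, R = R, T = T)
}

setMethod("show", "ProjectorModel", function(object) {
  cat("ProjectorModel\n  intrinsics: "); show(object@intrinsics)
  cat(sprintf("  T = (%.2f, %.2f, %.2f) mm\n", object@T[1], object@T[2],
              object@T[3]))
})

#' Plane in Hessian normal form
#'
#' The plane `p . n0 - d0 = 0` with unit normal `n0`.
#' @slot n0 unit normal.
#' @slot d0 offset (mm).
#' @export
setClass("Plane", representation(n0 = "numeric", d0 = "numeric"))

setValidity("Plane", function(object) {
  if (length(object@n0) != 3) return("n0 must have length 3")
  if (abs(sqrt(sum(object@n0^2)) - 1) > 1e-8) return("n0 must be unit length")
  TRUE
})

#' Construct a plane from normal and offset
#' @param n0 normal vector (normalized internally).
#' @param d0 offset such that `p . n0 - d0 = 0`; rescaled with `n0`.
#' @return A [Plane-class].
#' @export
plane3d <- function(n0, d0) {
  nl <- sqrt(sum(n0^2))
  new("Plane", n0 = n0 / nl, d0 = d0 / nl)
}

setMethod("show", "Plane", function(object) {
  cat(sprintf("Plane: n0 = (%.4f, %.4f, %.4f), d0 = %.3f mm\n",
              object@n0[1], object@n0[2], object@n0[3], object@d0))
})

#' Signed distances of points from a plane
#' @param plane a [Plane-class].
#' @param points N x 3 matrix.
#' @return Numeric vector `points %*% n0 - d0`.
#' @export
planeDistance <- function(plane, points) {
  drop(points %*% plane@n0) - plane@d0
}

#' Quad mesh on a fixed r x c vertex grid
#'
#' The self-organizing map's output surface: an `r x c` grid of 3D
#' vertices with implicit quadrilateral faces between grid neighbours, so
#' the mesh is hole-free by construction.
#'
#' @slot vertices numeric array `r x c x 3` (mm).
#' @export
setClass("QuadMesh", representation(vertices = "array"))

setValidity("QuadMesh", function(object) {
  d <- dim(object@vertices)
  if (length(d) != 3 || d[3] != 3) return("vertices must be r x c x 3")
  if (d[1] < 2 || d[2] < 2) return("grid must be at least 2 x 2")
  if (!all(is.finite(object@vertices))) return("vertices must be finite")
  TRUE
})

#' Construct a quad mesh
#' @param vertices `r x c x 3` array of vertex positions (mm).
#' @return A [QuadMesh-class].
#' @export
quadMesh <- function(vertices) new("QuadMesh", vertices = vertices)

#' Mesh vertices as a matrix
#' @param mesh a [QuadMesh-class].
#' @return `(r*c) x 3` matrix, column-major over the grid.
#' @export
meshVertices <- function(mesh) {
  d <- dim(mesh@vertices)
  matrix(mesh@vertices, d[1] * d[2], 3)
}

#' Grid dimensions of a quad mesh
#' @param mesh a [QuadMesh-class].
#' @return Integer vector `c(r, c)`.
#' @export
meshDim <- function(mesh) dim(mesh@vertices)[1:2]

setMethod("show", "QuadMesh", function(object) {
  d <- dim(object@vertices)
  cat(sprintf("QuadMesh: %d x %d vertex grid (%d quads)\n",
              d[1], d[2], (d[1] - 1) * (d[2] - 1)))
})

#' Coloured, labelled 3D point cloud with pixel provenance
#'
#' Links the reference-camera image to the reconstructed 3D points:
#' `pixelMap[v, u]` holds the row index into `points` of the 3D point
#' reconstructed at image pixel `(u, v)` (NA where reconstruction failed).
#'
#' @slot points N x 3 matrix (mm, reference camera frame).
#' @slot colors N x 3 matrix of RGB in \[0, 1\] (may have 0 rows).
#' @slot pixelMap integer H x W matrix of indices into `points`.
#' @slot labels factor of length N with levels wound/skin/background.
#' @export
setClass("WoundCloud",
  representation(points = "matrix", colors = "matrix", pixelMap = "matrix",
                 labels = "factor"))

setValidity("WoundCloud", function(object) {
  n <- nrow(object@points)
  if (ncol(object@points) != 3) return("points must be N x 3")
  pm <- object@pixelMap
  ix <- pm[!is.na(pm)]
  if (length(ix) && (min(ix) < 1 || max(ix) > n))
    return("pixelMap indexes outside the point set")
  if (length(object@labels) && length(object@labels) != n)
    return("labels must match the number of points")
  TRUE
})

#' Construct a wound cloud
#' @param points N x 3 matrix of 3D points (mm).
#' @param pixelMap integer H x W matrix mapping pixels to point rows (NA =
#'   invalid pixel).
#' @param colors optional N x 3 RGB matrix in \[0,1\].
#' @param labels optional factor (wound/skin/background) per point.
#' @return A [WoundCloud-class].
#' @export
woundCloud <- function(points, pixelMap,
                       colors = matrix(numeric(0), 0, 3),
                       labels = factor(rep("background", nrow(points)),
                                       levels = c("wound", "skin", "background"))) {
  new("WoundCloud", points = points, colors = colors,
      pixelMap = pixelMap, labels = labels)
}

#' Points of a cloud carrying a given label
#' @param cloud a [WoundCloud-class].
#' @param label one of `"wound"`, `"skin"`, `"background"`.
#' @return Matrix of the selected 3D points.
#' @export
cloudPoints <- function(cloud, label = NULL) {
  if (is.null(label)) return(cloud@points)
  cloud@points[cloud@labels == label, , drop = FALSE]
}

setMethod("show", "WoundCloud", function(object) {
  tab <- table(object@labels)
  cat(sprintf("WoundCloud: %d points (%s), pixel map %d x %d\n",
              nrow(object@points),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(object@pixelMap), ncol(object@pixelMap)))
})

#' Rigid transform
#' @slot R 3x3 proper rotation.
#' @slot T translation (mm).
#' @export
setClass("RigidTransform", representation(R = "matrix", T = "numeric"))

setValidity("RigidTransform", function(object) {
  if (!isRotation(object@R, tol = 1e-7)) return("R must be a proper rotation")
  if (length(object@T) != 3) return("T must have length 3")
  TRUE
})

#' Construct a rigid transform
#' @param R 3x3 rotation, `T` translation.
#' @param T translation vector (mm).
#' @return A [RigidTransform-class].
#' @export
rigidTransform <- function(R = diag(3), T = c(0, 0, 0))
  new("RigidTransform", R = R, T = T)

#' Apply a rigid transform to points
#' @param transform a [RigidTransform-class].
#' @param points N x 3 matrix.
#' @return Transformed N x 3 matrix.
#' @export
applyTransform <- function(transform, points) {
  sweep(points %*% t(transform@R), 2, transform@T, "+")
}

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@R)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.3f deg, T = (%.3f, %.3f, %.3f) mm\n",
              ang, object@T[1], object@T[2], object@T[3]))
})

#' Wound measurement report
#'
#' The six clinical parameters plus optional tissue composition and
#' acquisition metadata.
#'
#' @slot depth maximal depth (mm).
#' @slot perimeter 3D perimeter (mm).
#' @slot area3d mesh surface area (mm^2).
#' @slot areaProjected footprint area on the skin plane (mm^2).
#' @slot axisMajor,axisMinor main axes (mm), `axisMajor >= axisMinor`.
#' @slot volume cavity volume (mm^3).
#' @slot tissue named fractions per tissue class (may be empty).
#' @slot meta list of acquisition metadata (patient, date, working
#'   distance, configuration).
#' @export
setClass("WoundReport",
  representation(depth = "numeric", perimeter = "numeric", area3d = "numeric",
                 areaProjected = "numeric", axisMajor = "numeric",
                 axisMinor = "numeric", volume = "numeric",
                 tissue = "numeric", meta = "list"),
  prototype(tissue = numeric(0), meta = list()))

setValidity("WoundReport", function(object) {
  v <- c(object@depth, object@perimeter, object@area3d, object@areaProjected,
         object@axisMajor, object@axisMinor, object@volume)
  if (any(v < 0)) return("all parameters must be >= 0")
  if (object@axisMajor < object@axisMinor - 1e-9)
    return("axisMajor must be >= axisMinor")
  if (length(object@tissue) &&
      abs(sum(object@tissue) - 1) > 1e-6)
    return("tissue fractions must sum to 1")
  TRUE
})

#' Construct a wound report
#' @param depth,perimeter,area3d,areaProjected,axisMajor,axisMinor,volume
#'   the six clinical parameters (mm / mm^2 / mm^3).
#' @param tissue optional named tissue fractions summing to 1.
#' @param meta optional metadata list.
#' @return A [WoundReport-class].
#' @export
woundReport <- function(depth, perimeter, area3d, areaProjected,
                        axisMajor, axisMinor, volume,
                        tissue = numeric(0), meta = list()) {
  new("WoundReport", depth = depth, perimeter = perimeter, area3d = area3d,
      areaProjected = areaProjected, axisMajor = axisMajor,
      axisMinor = axisMinor, volume = volume, tissue = tissue, meta = meta)
}

#' Wound report as a named numeric vector
#' @param report a [WoundReport-class].
#' @return Named vector of the six parameters (units embedded in names).
#' @export
reportValues <- function(report) {
  c(depth_mm = report@depth, perimeter_mm = report@perimeter,
    area3d_mm2 = report@area3d, areaproj_mm2 = report@areaProjected,
    axis_major_mm = report@axisMajor, axis_minor_mm = report@axisMinor,
    volume_mm3 = report@volume)
}

setMethod("show", "WoundReport", function(object) {
  cat("WoundReport\n")
  v <- reportValues(object)
  for (k in names(v)) cat(sprintf("  %-14s %10.3f\n", k, v[[k]]))
  if (length(object@tissue)) {
    cat("  tissue:",
        paste(sprintf("%s %.1f%%", names(object@tissue),
                      100 * object@tissue), collapse = ", "), "\n")
  }
})

#' Synthetic wound phantom
#'
#' An analytic wound on a flat skin plane (z = 0, cavity depth positive
#' towards +z, i.e. away from the camera): a footprint predicate, a depth
#' field, a tissue label field, and the ground-truth parameters evaluated
#' in closed form or by high-resolution numerical integration.
#'
#' @slot name phantom identifier ("A".."D" for the built-ins).
#' @slot shape footprint family.
#' @slot params parameter list used to build the fields.
#' @slot inside `function(x, y) -> logical` footprint membership.
#' @slot depth `function(x, y) -> depth (mm, >= 0)`.
#' @slot tissueMap `function(x, y) -> character` tissue label.
#' @slot boundary dense M x 2 matrix tracing the footprint boundary (mm).
#' @slot domain list with `xlim`, `ylim` (mm) covering wound + skin margin.
#' @slot truth the ground-truth [WoundReport-class].
#' @slot seed integer seed used for randomized phantoms (NA otherwise).
#' @export
setClass("PhantomSpec",
  representation(name = "character", shape = "character", params = "list",
                 inside = "function", depth = "function",
                 tissueMap = "function", boundary = "matrix",
                 domain = "list", truth = "WoundReport", seed = "numeric"))

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s' (%s)\n", object@name, object@shape))
  cat("  ground truth:\n")
  v <- reportValues(object@truth)
  for (k in names(v)) cat(sprintf("    %-14s %10.3f\n", k, v[[k]]))
})

#' Rater study container
#'
#' Measurements collected by simulated raters over a set of phantoms, one
#' slice per clinical parameter.
#'
#' @slot measurements numeric array `phantom x rater x parameter`.
#' @slot truth matrix `phantom x parameter` of ground-truth values.
#' @export
setClass("RaterStudy",
  representation(measurements = "array", truth = "matrix"))

setMethod("show", "RaterStudy", function(object) {
  d <- dim(object@measurements)
  cat(sprintf("RaterStudy: %d phantoms x %d raters x %d parameters\n",
              d[1], d[2], d[3]))
})
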