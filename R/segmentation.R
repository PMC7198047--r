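#' Rasterize a closed polygon into a binary mask
#'
#' Even-odd fill over pixel centres (0-based pixel convention).
#' @param vertices M x 2 matrix of polygon vertices `(x, y)` in pixels,
#'   implicitly closed.
#' @param width,height mask size in pixels.
#' @return Logical `height x width` matrix.
#' @export
polygonMask <- function(vertices, width, height) {
  if (nrow(vertices) < 3) stop("polygon needs at least 3 vertices")
  xs <- vertices[, 1]; ys <- vertices[, 2]
  n <- length(xs)
  xs2 <- c(xs, xs[1]); ys2 <- c(ys, ys[1])
  g <- expand.grid(x = 0:(width - 1), y = 0:(height - 1))
  inside <- rep(FALSE, nrow(g))
  for (k in seq_len(n)) {
    x1 <- xs2[k]; y1 <- ys2[k]; x2 <- xs2[k + 1]; y2 <- ys2[k + 1]
    cross <- ((y1 > g$y) != (y2 > g$y)) &
      (g$x < (x2 - x1) * (g$y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross)
  }
  matrix(inside, height, width, byrow = TRUE)
}

#' Refine a coarse wound contour with a region-based active contour
#'
#' Evolves a two-phase Chan-Vese active contour (morphological level-set
#' discretization), initialized from the user's coarse polygon; the
#' curve stops on the wound boundary without requiring an edge map,
#' which suits the smooth boundaries of wound beds. For RGB input the
#' vector-valued extension is used (region mean colours instead of mean
#' intensities), which keeps bright slough inside the wound region even
#' when its intensity resembles the surrounding skin. The returned mask
#' is the largest connected foreground region overlapping the
#' initialization.
#'
#' @param image RGB array (H x W x 3) or grayscale matrix, values in
#'   \[0,1\].
#' @param coarse M x 2 matrix of coarse contour vertices (pixels) or a
#'   logical initialization mask.
#' @param maxIter maximum iterations (default 500).
#' @param tol convergence tolerance on the mean level-set update
#'   (default 1e-3).
#' @param mu curvature (smoothness) weight (default 0.25).
#' @param lambda1,lambda2 region data weights (default 1, 1).
#' @param fallback if TRUE return the coarse polygon mask (with a
#'   warning) instead of erroring when refinement fails.
#' @return Logical wound mask; attribute `iterations` records the number
#'   of evolution steps run.
#' @export
refineContour <- function(image, coarse, maxIter = 500L, tol = 1e-3,
                          mu = 0.25, lambda1 = 1, lambda2 = 1,
                          fallback = FALSE) {
  if (length(dim(image)) == 2) image <- array(image, c(dim(image), 1))
  H <- dim(image)[1]; W <- dim(image)[2]; K <- dim(image)[3]
  init <- if (is.matrix(coarse) && is.logical(coarse)) coarse
          else polygonMask(coarse, W, H)
  if (!any(init)) stop("coarse contour rasterizes to an empty mask")
  if (diff(range(image)) < 1e-6) {
    if (fallback) { warning("uniform image; returning coarse mask"); return(init) }
    stop("refinement failure: image has no two-phase partition")
  }
  smoothing <- max(1L, as.integer(round(mu / 0.25)))
  ev <- chanvese_cpp(as.numeric(image), H, W, K,
                     matrix(as.integer(init), H, W), lambda1, lambda2,
                     smoothing, maxIter = as.integer(maxIter), tol = tol)
  mask <- ev$u > 0
  mask <- largestOverlappingComponent(mask, init)
  if (is.null(mask) || !any(mask)) {
    if (fallback) { warning("refinement failed; returning coarse mask"); return(init) }
    stop("refinement failure: empty region")
  }
  attr(mask, "iterations") <- ev$iterations
  mask
}

# largest connected component of `mask` that overlaps `init`; NULL if none
largestOverlappingComponent <- function(mask, init) {
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask * 1)
  labs <- sort(unique(as.vector(lab[init & mask])))
  labs <- labs[labs > 0]
  if (!length(labs)) return(NULL)
  sizes <- vapply(labs, function(l) sum(lab == l), numeric(1))
  as.matrix(lab == labs[which.max(sizes)])
}

#' Expand a wound mask into a surrounding skin band
#'
#' Dilates the wound mask isotropically until the enclosed area reaches
#' `factor` times the wound area (default 1.5, i.e. the region grows by
#' 50% of the segmented area) and returns the annulus between the dilated
#' region and the wound, which samples the surrounding healthy skin. The
#' remaining image area (background) is discarded by the caller.
#'
#' @param mask logical wound mask.
#' @param factor target enclosed-area ratio (default 1.5).
#' @return Logical skin-band mask; warns when the band is clipped by the
#'   image border.
#' @export
expandROI <- function(mask, factor = 1.5) {
  if (!any(mask)) stop("empty wound mask")
  target <- factor * sum(mask)
  cur <- mask
  brush <- EBImage::makeBrush(3, "diamond")
  guard <- 0
  while (sum(cur) < target) {
    cur <- as.matrix(EBImage::dilate(cur * 1, brush)) > 0
    if (sum(cur) >= target) break
    if (all(cur)) break
    guard <- guard + 1
    if (guard > max(dim(mask))) break
  }
  if (any(cur[1, ]) || any(cur[nrow(cur), ]) ||
      any(cur[, 1]) || any(cur[, ncol(cur)]))
    warning("skin band clipped by image border")
  cur & !mask
}

#' Lift 2D masks to labelled 3D points
#'
#' Assigns wound/skin labels to the 3D points selected by the wound and
#' skin-band masks through the pixel provenance map; everything else is
#' background. Pixels with no valid reconstruction are skipped.
#'
#' @param woundMask,skinMask logical masks (same size as the pixel map),
#'   must be disjoint.
#' @param pixelMap integer H x W matrix of indices into `points`.
#' @param points N x 3 matrix of 3D points, or a [WoundCloud-class]
#'   (whose map and points are then used).
#' @return A [WoundCloud-class] with labels set.
#' @export
liftTo3d <- function(woundMask, skinMask, pixelMap, points) {
  if (is(pixelMap, "WoundCloud")) {
    cl <- pixelMap; pixelMap <- cl@pixelMap; points <- cl@points
    colors <- cl@colors
  } else if (is(points, "WoundCloud")) {
    cl <- points; colors <- cl@colors; points <- cl@points
  } else colors <- matrix(numeric(0), 0, 3)
  if (any(woundMask & skinMask)) stop("wound and skin masks must be disjoint")
  if (!all(dim(woundMask) == dim(pixelMap)))
    stop("mask shape must match the pixel map")
  lab <- factor(rep("background", nrow(points)),
                levels = c("wound", "skin", "background"))
  wIdx <- pixelMap[woundMask]
  sIdx <- pixelMap[skinMask]
  nbadw <- sum(is.na(wIdx))
  wIdx <- wIdx[!is.na(wIdx)]
  sIdx <- sIdx[!is.na(sIdx)]
  if (!length(wIdx)) stop("empty selection: no valid wound points")
  if (nbadw > 0)
    warning(sprintf("%d wound pixels had no valid 3D point", nbadw))
  lab[sIdx] <- "skin"
  lab[wIdx] <- "wound"   # wound wins where masks map to the same point
  woundCloud(points, pixelMap, colors = colors, labels = lab)
}
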