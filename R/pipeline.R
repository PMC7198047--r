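#' Pipeline configuration
#'
#' Bundles the tunable parameters of the assessment pipeline with their
#' defaults.
#'
#' @param gridR,gridC SOM mesh grid (default 64 x 64).
#' @param somEpochs SOM training epochs (default 10).
#' @param cvMaxIter,cvTol,cvMu contour refinement controls.
#' @param expandFactor skin-band enclosed-area factor (default 1.5).
#' @param alpha alpha-shape radius (mm); NULL = automatic.
#' @param correction apply digitization-bias corrections (default TRUE).
#' @param seed seed driving the SOM sample order.
#' @return A named list.
#' @export
woundConfig <- function(gridR = 64L, gridC = 64L, somEpochs = 10L,
                        cvMaxIter = 500L, cvTol = 1e-3, cvMu = 0.25,
                        expandFactor = 1.5, alpha = NULL,
                        correction = TRUE, seed = 1L) {
  list(gridR = gridR, gridC = gridC, somEpochs = somEpochs,
       cvMaxIter = cvMaxIter, cvTol = cvTol, cvMu = cvMu,
       expandFactor = expandFactor, alpha = alpha,
       correction = correction, seed = seed)
}

#' Assess a wound from a cloud, image and coarse contour
#'
#' The full measurement chain: refine the coarse contour on the
#' reference image (region-based active contour), expand the wound
#' region by 50% of its area to collect surrounding skin, lift both
#' regions to labelled 3D points, fit the SOM quad-mesh to the wound
#' points and the total-least-squares plane to the skin points, and
#' compute the six clinical parameters (plus, when tissue seeds are
#' given, the tissue composition over the 3D surface).
#'
#' @param cloud unlabelled [WoundCloud-class] (points + pixel map).
#' @param image reference-camera RGB array aligned with the pixel map.
#' @param coarse coarse contour polygon (pixels) or initialization mask.
#' @param config list from [woundConfig()].
#' @param tissueSeeds optional data frame `x`, `y`, `label` of tissue
#'   seed picks.
#' @param meta metadata stored in the report.
#' @return A [WoundReport-class]; attributes `mesh`, `cloud`,
#'   `woundMask` expose the intermediates.
#' @export
assessWound <- function(cloud, image, coarse, config = woundConfig(),
                        tissueSeeds = NULL, meta = list()) {
  woundMask <- refineContour(image, coarse, maxIter = config$cvMaxIter,
                             tol = config$cvTol, mu = config$cvMu,
                             fallback = TRUE)
  skinMask <- expandROI(woundMask, factor = config$expandFactor)
  cloud <- liftTo3d(woundMask, skinMask, cloud@pixelMap, cloud)
  wound <- cloudPoints(cloud, "wound")
  # area-element sampling weights: steep walls are foreshortened in the
  # image grid and would otherwise be under-resolved by the map
  aw <- pixelAreaWeights(cloud)
  widx <- cloud@pixelMap[woundMask]
  wvec <- rep(NA_real_, nrow(cloud@points))
  wvec[widx[!is.na(widx)]] <- aw[woundMask][!is.na(widx)]
  weights <- wvec[cloud@labels == "wound"]
  # traced wound rim at the half-pixel crack, lifted and smoothed:
  # anchors the mesh border at the level where the wound meets the skin
  skinPlane <- orientPlaneTowards(fitSkinPlane(cloudPoints(cloud, "skin")),
                                  wound)
  bnd3 <- rimAnchorPolygon(woundMask, cloud@pixelMap, cloud@points,
                           plane = skinPlane)
  mesh <- suppressWarnings(
    fitSOMMesh(wound, gridR = config$gridR, gridC = config$gridC,
               epochs = config$somEpochs, weights = weights,
               boundary = if (config$correction) bnd3 else NULL,
               seed = config$seed, borderCorrection = config$correction))
  tissue <- numeric(0)
  if (!is.null(tissueSeeds)) {
    sp <- slicSuperpixels(image, woundMask,
                          nSegments = max(4L, round(sum(woundMask) / 200)))
    cls <- classifyTissue(image, sp, tissueSeeds)
    tissue <- tissuePercentages3d(cls$labels, cloud)
  }
  rep <- computeReport(cloud, mesh, woundMask, alpha = config$alpha,
                       tissue = tissue, meta = meta,
                       correction = config$correction)
  attr(rep, "mesh") <- mesh
  attr(rep, "cloud") <- cloud
  attr(rep, "woundMask") <- woundMask
  rep
}

#' Measure a phantom through the full pipeline
#'
#' Convenience wrapper: sample a device-like cloud from the phantom,
#' render its reference image, build a jittered coarse contour, and run
#' [assessWound()].
#'
#' @param phantom a [PhantomSpec-class].
#' @param spacing lateral sampling pitch (mm).
#' @param noiseSigma depth noise SD (mm).
#' @param seed seed driving sampling noise, rendering noise, contour
#'   jitter and SOM ordering.
#' @param pose optional rigid pose of the phantom.
#' @param config pipeline configuration; its seed is overridden by
#'   `seed`.
#' @param withTissue also classify tissue with one auto-placed seed per
#'   true class.
#' @return A [WoundReport-class] (see [assessWound()]).
#' @export
measurePhantom <- function(phantom, spacing = 0.2, noiseSigma = 0.1,
                           seed = 1L, pose = NULL,
                           config = woundConfig(), withTissue = FALSE) {
  config$seed <- seed
  smp <- sampleCloud(phantom, spacing = spacing, noiseSigma = noiseSigma,
                     pose = pose, seed = seed)
  img <- renderWoundImage(phantom, spacing = spacing, seed = seed + 1L)
  coarse <- coarseContour(phantom, spacing = spacing, seed = seed + 2L)
  seeds <- NULL
  if (withTissue) seeds <- autoTissueSeeds(img$tissueMasks)
  assessWound(smp$cloud, img$image, coarse, config = config,
              tissueSeeds = seeds,
              meta = list(phantom = phantom@name, spacing = spacing,
                          noiseSigma = noiseSigma, seed = seed))
}

#' Wound rim anchor polygon
#'
#' The traced wound boundary runs through the outermost pixels *inside*
#' the wound; the physical rim lies half a pixel further out, where the
#' wound surface meets the skin. For each boundary pixel this function
#' finds its outward neighbour (local 2D boundary normal), and anchors
#' the rim at the midpoint of the two lifted 3D points when the surface
#' is continuous across the crack. Where the depth jump exceeds
#' `jumpFactor` times the interior depth step (a cliff, e.g. the deep
#' edge of a ramp wound that the camera cannot sample), only the
#' in-plane half-pixel offset is applied and the depth is kept.
#'
#' @param mask logical wound mask.
#' @param pixelMap,points pixel provenance map and 3D points.
#' @param plane optional skin [Plane-class]; when given, continuous rim
#'   anchors are placed where the in-to-out segment crosses the skin
#'   level (the physical wound rim) instead of at the segment midpoint.
#' @param jumpFactor cliff detection threshold (default 3).
#' @param jumpFloor minimum depth step (mm) treated as continuous
#'   regardless of the local slope (default 0.5), guarding against the
#'   noise floor.
#' @param smoothWindow,normalWindow smoothing as in [liftBoundary3d()].
#' @return Ordered closed M x 3 polygon of rim anchor points.
#' @export
rimAnchorPolygon <- function(mask, pixelMap, points, plane = NULL,
                             jumpFactor = 3, jumpFloor = 0.5,
                             smoothWindow = 3L, normalWindow = 7L) {
  b2 <- tracePerimeter2d(mask)
  n <- nrow(b2)
  if (n < 8) {
    return(liftBoundary3d(b2, pixelMap, points, smoothWindow, normalWindow))
  }
  H <- nrow(mask); W <- ncol(mask)
  getIdx <- function(x, y) {
    ok <- x >= 0 & x < W & y >= 0 & y < H
    out <- rep(NA_integer_, length(x))
    out[ok] <- pixelMap[cbind(y[ok] + 1, x[ok] + 1)]
    out
  }
  km <- function(k, d) ((k - 1 + d) %% n) + 1
  anchors <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    tx <- b2[km(k, 2), 1] - b2[km(k, -2), 1]
    ty <- b2[km(k, 2), 2] - b2[km(k, -2), 2]
    tl <- sqrt(tx^2 + ty^2)
    if (tl < 1e-9) next
    nx <- ty / tl; ny <- -tx / tl
    ox <- b2[k, 1] + round(nx); oy <- b2[k, 2] + round(ny)
    ins <- ox >= 0 & ox < W & oy >= 0 & oy < H && isTRUE(mask[oy + 1, ox + 1])
    if (ins) { nx <- -nx; ny <- -ny; ox <- b2[k, 1] + round(nx); oy <- b2[k, 2] + round(ny) }
    iIn <- getIdx(b2[k, 1], b2[k, 2])
    iOut <- getIdx(ox, oy)
    iIn2 <- getIdx(b2[k, 1] - round(nx), b2[k, 2] - round(ny))
    if (is.na(iIn)) next
    pIn <- points[iIn, ]
    if (is.na(iOut)) { anchors[k, ] <- pIn; next }
    pOut <- points[iOut, ]
    jump <- abs(pIn[3] - pOut[3])
    step <- if (!is.na(iIn2)) abs(pIn[3] - points[iIn2, 3]) else 0
    if (jump <= max(jumpFactor * step, jumpFloor)) {
      if (!is.null(plane)) {
        sIn <- sum(pIn * plane@n0) - plane@d0
        sOut <- sum(pOut * plane@n0) - plane@d0
        if (abs(sIn - sOut) > 0.05) {
          t <- min(max(sIn / (sIn - sOut), 0), 1)
          anchors[k, ] <- pIn + t * (pOut - pIn)
        } else anchors[k, ] <- (pIn + pOut) / 2
      } else anchors[k, ] <- (pIn + pOut) / 2
    } else {
      v <- (pOut - pIn) / 2
      v[3] <- 0
      anchors[k, ] <- pIn + v
    }
  }
  keep <- stats::complete.cases(anchors)
  P <- anchors[keep, , drop = FALSE]
  m <- nrow(P)
  pitch <- medianSpacing(P)
  circSmooth <- function(v, w) {
    if (w <= 1 || m <= w) return(v)
    h <- (w - 1) %/% 2
    ext <- c(v[(m - h + 1):m], v, v[1:h])
    stats::filter(ext, rep(1 / w, w), sides = 2)[(h + 1):(h + m)]
  }
  pca <- prcomp(P, center = TRUE)
  Q <- pca$x
  Q[, 1] <- circSmooth(Q[, 1], smoothWindow)
  Q[, 2] <- circSmooth(Q[, 2], smoothWindow)
  Q[, 3] <- circSmooth(Q[, 3], normalWindow)
  P <- sweep(Q %*% t(pca$rotation), 2, pca$center, "+")
  attr(P, "pitch") <- pitch
  P
}

# one seed per true tissue class at the centroid-most pixel of its mask
autoTissueSeeds <- function(tissueMasks) {
  cls <- setdiff(names(tissueMasks), "skin")
  out <- do.call(rbind, lapply(cls, function(cl) {
    m <- tissueMasks[[cl]]
    ij <- which(m, arr.ind = TRUE)
    ctr <- colMeans(ij)
    d2 <- (ij[, 1] - ctr[1])^2 + (ij[, 2] - ctr[2])^2
    # the centroid can fall outside a non-convex class region; take the
    # masked pixel closest to it
    best <- ij[which.min(d2), ]
    data.frame(x = best[2] - 1, y = best[1] - 1, label = cl)
  }))
  out
}

#' Simulate a multi-rater phantom study
#'
#' Emulates independent users measuring each phantom once: every
#' rater-phantom cell draws its own working distance, small orientation
#' jitter of the device, sampling noise, contour jitter and SOM
#' ordering, then runs the full pipeline and collects the six clinical
#' parameters.
#'
#' @param phantoms list of [PhantomSpec-class] objects.
#' @param nRaters number of raters (default 11).
#' @param spacing,noiseSigma sampling parameters.
#' @param tiltSdDeg SD of the device tilt jitter in degrees (default 2).
#' @param distanceRange working distance range sampled per rater (mm).
#' @param seed master seed.
#' @return A [RaterStudy-class]; cells from failed pipeline runs are
#'   recorded as NA with a warning.
#' @export
simulateRaterStudy <- function(phantoms, nRaters = 11L, spacing = 0.2,
                               noiseSigma = 0.1, tiltSdDeg = 2,
                               distanceRange = c(150, 350), seed = 1L) {
  pn <- c("depth_mm", "perimeter_mm", "area3d_mm2", "areaproj_mm2",
          "axis_major_mm", "axis_minor_mm", "volume_mm3")
  M <- array(NA_real_, c(length(phantoms), nRaters, length(pn)),
             dimnames = list(vapply(phantoms, function(p) p@name, ""),
                             paste0("rater", seq_len(nRaters)), pn))
  truth <- t(vapply(phantoms, function(p) reportValues(p@truth),
                    numeric(length(pn))))
  colnames(truth) <- pn
  for (i in seq_along(phantoms)) {
    for (r in seq_len(nRaters)) {
      cellSeed <- seed + 1000L * i + r
      pose <- withSeed(cellSeed, {
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        rigidTransform(rotationMatrix(ax, rnorm(1, sd = tiltSdDeg)),
                       c(0, 0, runif(1, distanceRange[1], distanceRange[2]) - 200))
      })
      rep <- try(measurePhantom(phantoms[[i]], spacing = spacing,
                                noiseSigma = noiseSigma, seed = cellSeed,
                                pose = pose), silent = TRUE)
      if (inherits(rep, "try-error")) {
        warning(sprintf("pipeline failed for phantom %s rater %d; recorded NA",
                        dimnames(M)[[1]][i], r))
      } else {
        M[i, r, ] <- reportValues(rep)
      }
    }
  }
  new("RaterStudy", measurements = M, truth = truth)
}
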