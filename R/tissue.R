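#' Chroma features in CIELAB
#'
#' Converts masked pixels from sRGB to CIELAB (D65) and keeps only the
#' chroma channels `(a, b)`, which removes the brightness contribution
#' (shadows, uneven illumination) from subsequent clustering.
#'
#' @param image RGB array H x W x 3 in \[0,1\].
#' @param mask logical mask selecting the pixels (default: all).
#' @return Matrix with columns `a`, `b`, one row per masked pixel (in
#'   column-major mask order).
#' @export
toAbFeatures <- function(image, mask = NULL) {
  if (length(dim(image)) != 3) stop("image must be H x W x 3")
  H <- dim(image)[1]; W <- dim(image)[2]
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  rgb <- cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  out <- lab[, 2:3, drop = FALSE]
  colnames(out) <- c("a", "b")
  out
}

# full Lab for internal use (SLIC needs L too)
toLabChannels <- function(image) {
  H <- dim(image)[1]; W <- dim(image)[2]
  rgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1], H, W), a = matrix(lab[, 2], H, W),
       b = matrix(lab[, 3], H, W))
}

#' SLIC superpixels over a masked region
#'
#' Simple linear iterative clustering: locality-constrained k-means in
#' `(L, a, b, x, y)` initialized on a regular grid at spacing
#' `sqrt(area / n)`, restricted to the mask, followed by a connectivity
#' clean-up that merges stray fragments into adjacent superpixels.
#'
#' @param image RGB array H x W x 3 in \[0,1\].
#' @param mask logical region to segment (default: whole image).
#' @param nSegments target number of superpixels.
#' @param compactness trade-off between colour and spatial proximity
#'   (default 10, CIELAB units).
#' @param iters k-means sweeps (default 10).
#' @return Integer H x W label matrix (NA outside the mask); labels are
#'   1..k with every masked pixel assigned to exactly one superpixel.
#' @export
slicSuperpixels <- function(image, mask = NULL, nSegments = 100,
                            compactness = 10, iters = 10L) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  npix <- sum(mask)
  if (nSegments < 1) stop("nSegments must be >= 1")
  if (nSegments > npix) stop("more segments requested than masked pixels")
  lab <- toLabChannels(image)
  S <- sqrt(npix / nSegments)
  # grid-spaced seeds inside the mask
  rows <- seq(1 + S / 2, H, by = S)
  cols <- seq(1 + S / 2, W, by = S)
  seeds <- expand.grid(r = round(rows), c = round(cols))
  seeds <- seeds[mask[cbind(seeds$r, seeds$c)], , drop = FALSE]
  if (!nrow(seeds)) {
    # fall back to the densest masked pixel
    ij <- which(mask, arr.ind = TRUE)
    seeds <- data.frame(r = ij[1, 1], c = ij[1, 2])
  }
  labels <- slic_cpp(lab$L, lab$a, lab$b, mask,
                     as.matrix(seeds), S, compactness, as.integer(iters))
  labels <- slic_connectivity_cpp(labels)
  labels[labels == 0L] <- NA_integer_
  labels
}

#' Classify tissue from seeded superpixel clustering
#'
#' K-means on the mean CIELAB chroma `(a, b)` of each superpixel, with
#' the user-picked seed pixels as initial centroids — one seed (or more)
#' per tissue class the clinician selects. Each superpixel receives the
#' tissue label of the seed class its final centroid originated from.
#' Working in chroma only makes the labels invariant to brightness.
#'
#' @param image RGB array H x W x 3 in \[0,1\].
#' @param superpixels label matrix from [slicSuperpixels()].
#' @param seeds data frame with columns `x`, `y` (pixels, 0-based) and
#'   `label` (character, e.g. granulation/slough/necrosis).
#' @return List with `labels` (character H x W matrix, NA outside mask),
#'   `superpixelLabel` (character vector per superpixel), and `classes`.
#' @export
classifyTissue <- function(image, superpixels, seeds) {
  classes <- unique(as.character(seeds$label))
  if (length(classes) > 3) stop("at most 3 tissue classes supported")
  ab <- toAbFeatures(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  sp <- as.vector(superpixels)
  ok <- !is.na(sp)
  k <- max(sp[ok])
  spMean <- cbind(
    a = tapply(ab[ok, "a"], sp[ok], mean),
    b = tapply(ab[ok, "b"], sp[ok], mean))
  # seed centroids: mean (a,b) of the seed pixels per class
  cent <- matrix(NA_real_, length(classes), 2,
                 dimnames = list(classes, c("a", "b")))
  for (cl in classes) {
    sel <- seeds$label == cl
    px <- cbind(seeds$y[sel] + 1, seeds$x[sel] + 1)
    rgb <- cbind(image[, , 1][px], image[, , 2][px], image[, , 3][px])
    labv <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
    cent[cl, ] <- colMeans(labv[, 2:3, drop = FALSE])
  }
  if (length(classes) > 1 &&
      min(stats::dist(cent)) < 1e-6)
    stop("degenerate seeds: two classes have identical chroma")
  if (length(classes) == 1) {
    spLab <- rep(classes, nrow(spMean))
  } else {
    km <- kmeans(spMean, centers = cent, iter.max = 100,
                 algorithm = "Lloyd")
    spLab <- classes[km$cluster]
  }
  names(spLab) <- rownames(spMean)
  out <- matrix(NA_character_, H, W)
  out[ok] <- spLab[as.character(sp[ok])]
  list(labels = out, superpixelLabel = spLab, classes = classes)
}

#' Per-pixel 3D surface area weights
#'
#' Local surface area represented by each valid pixel of the provenance
#' map: the cross-product magnitude of the finite-difference surface
#' tangents at the pixel's 3D point, times the pixel footprint. Used to
#' weight tissue fractions by true 3D area rather than image area, which
#' matters on steep walls seen foreshortened by the camera.
#'
#' @param cloud a [WoundCloud-class].
#' @return Numeric H x W matrix of area weights (NA outside the map).
#' @export
pixelAreaWeights <- function(cloud) {
  pm <- cloud@pixelMap
  H <- nrow(pm); W <- ncol(pm)
  P <- cloud@points
  gx <- array(NA_real_, c(H, W, 3))
  gy <- array(NA_real_, c(H, W, 3))
  idx <- matrix(NA_integer_, H, W)
  idx[] <- pm
  getp <- function(di, dj) {
    sh <- matrix(NA_integer_, H, W)
    ri <- seq_len(H) + di; cj <- seq_len(W) + dj
    okr <- ri >= 1 & ri <= H; okc <- cj >= 1 & cj <= W
    sh[okr, okc] <- idx[ri[okr], cj[okc]]
    sh
  }
  right <- getp(0, 1); left <- getp(0, -1)
  down <- getp(1, 0); up <- getp(-1, 0)
  # central differences where possible, one-sided at borders
  diffP <- function(aIdx, bIdx, fallbackA, fallbackB) {
    res <- array(NA_real_, c(H, W, 3))
    a <- aIdx; b <- bIdx
    useC <- !is.na(a) & !is.na(b)
    useF <- !useC & !is.na(fallbackA) & !is.na(fallbackB)
    for (k in 1:3) {
      m <- matrix(NA_real_, H, W)
      m[useC] <- (P[a[useC], k] - P[b[useC], k]) / 2
      m[useF] <- P[fallbackA[useF], k] - P[fallbackB[useF], k]
      res[, , k] <- m
    }
    res
  }
  du <- diffP(right, left, right, idx)
  du2 <- diffP(right, left, idx, left)
  for (k in 1:3) { m <- du[, , k]; m2 <- du2[, , k]; m[is.na(m)] <- m2[is.na(m)]; du[, , k] <- m }
  dv <- diffP(down, up, down, idx)
  dv2 <- diffP(down, up, idx, up)
  for (k in 1:3) { m <- dv[, , k]; m2 <- dv2[, , k]; m[is.na(m)] <- m2[is.na(m)]; dv[, , k] <- m }
  cx <- du[, , 2] * dv[, , 3] - du[, , 3] * dv[, , 2]
  cy <- du[, , 3] * dv[, , 1] - du[, , 1] * dv[, , 3]
  cz <- du[, , 1] * dv[, , 2] - du[, , 2] * dv[, , 1]
  w <- sqrt(cx^2 + cy^2 + cz^2)
  w[is.na(pm)] <- NA_real_
  w
}

#' Tissue composition over the 3D wound surface
#'
#' Fractions of each tissue class weighted by the 3D surface area each
#' pixel represents, so steep regions are not under-counted.
#'
#' @param labels character H x W tissue label matrix (from
#'   [classifyTissue()]).
#' @param cloud the [WoundCloud-class] providing geometry; weights from
#'   [pixelAreaWeights()] unless supplied.
#' @param weights optional precomputed H x W area-weight matrix.
#' @return Named numeric vector of fractions summing to 1.
#' @export
tissuePercentages3d <- function(labels, cloud, weights = NULL) {
  if (is.null(weights)) weights <- pixelAreaWeights(cloud)
  ok <- !is.na(labels) & !is.na(weights)
  if (!any(ok)) stop("no labelled pixels with valid geometry")
  tot <- tapply(weights[ok], labels[ok], sum)
  s <- sum(tot)
  if (s <= 0) stop("zero total surface area")
  frac <- as.numeric(tot) / s
  names(frac) <- names(tot)
  frac
}
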