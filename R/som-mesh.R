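#' Fit a self-organizing map quad-mesh to a point cloud
#'
#' Trains a classic Kohonen map whose nodes are the vertices of an
#' `r x c` quad-mesh and whose weights are 3D coordinates, so the trained
#' grid is a smooth, hole-free surface adapted to the cloud. Per sample
#' the best-matching node (Euclidean distance) and its Gaussian grid
#' neighbourhood are moved towards the sample, with exponentially
#' decaying learning rate and neighbourhood radius. The grid is
#' initialized as a planar lattice spanning the cloud's two leading
#' principal directions, which keeps the topology unfolded; a fold check
#' (negative quad areas in the PCA parameter plane) triggers one
#' restarted fit with a jittered initialization.
#'
#' Because image-derived clouds only sample the surface at pixel centres
#' and converged border nodes sit at the centroid of their data cells,
#' the mesh rim systematically falls about half a node gap plus half a
#' sampling pitch inside the true wound rim. With
#' `borderCorrection = TRUE` (default) border vertices are extrapolated
#' outward by that amount along the local grid direction.
#'
#' @param points N x 3 matrix of 3D points (mm).
#' @param gridR,gridC grid size (default 64 x 64).
#' @param epochs training epochs over the shuffled cloud (default 10).
#' @param lr learning rate schedule `c(start, end)` (default 0.5 to 0.01).
#' @param radius neighbourhood radius schedule in grid units; default
#'   `max(gridR, gridC)/2` decaying to 1.
#' @param weights optional per-point sampling weights. Image-derived
#'   clouds sample steep surface regions sparsely (foreshortening);
#'   weighting samples by the local 3D area element (see
#'   [pixelAreaWeights()]) makes the node density follow true surface
#'   area so walls are meshed at full resolution.
#' @param boundary optional ordered M x 3 closed polygon of the wound's
#'   traced 3D boundary. When given, the trained grid rim is anchored
#'   onto this curve (each rim vertex moves to its closest point on the
#'   polygon), which removes the map's border contraction exactly at the
#'   wound rim; the generic outward extrapolation is then skipped.
#' @param seed integer seed for the sample shuffling (deterministic mesh
#'   for a fixed seed); NULL uses the current RNG stream.
#' @param borderCorrection extrapolate border vertices outward (see
#'   Details).
#' @param recordError also compute the mean point-to-mesh-vertex distance
#'   after each epoch (attribute `epochError`; slows training).
#' @return A [QuadMesh-class]; attribute `epochError` when requested.
#' @export
fitSOMMesh <- function(points, gridR = 64L, gridC = 64L, epochs = 10L,
                       lr = c(0.5, 0.01), radius = NULL, weights = NULL,
                       boundary = NULL, seed = NULL,
                       borderCorrection = TRUE, recordError = FALSE) {
  n <- nrow(points)
  if (n < 9) stop("degenerate input: need at least 9 points")
  if (epochs < 1) stop("epochs must be >= 1")
  if (gridR < 2 || gridC < 2) stop("grid must be at least 2 x 2")
  rng <- apply(points, 2, function(v) diff(range(v)))
  if (max(rng) < 1e-9) stop("degenerate input: all points identical")
  if (n < gridR * gridC)
    warning("fewer points than grid nodes; the mesh interpolates the cloud")
  if (is.null(radius)) radius <- c(max(gridR, gridC) / 2, 1)

  if (!is.null(weights)) {
    weights <- pmax(weights, 0)
    weights[!is.finite(weights)] <- 0
    if (sum(weights) <= 0) weights <- NULL
  }
  drawOrder <- function() {
    if (is.null(weights)) as.integer(replicate(epochs, sample.int(n)))
    else as.integer(sample.int(n, n * epochs, replace = TRUE,
                               prob = weights))
  }
  pca <- prcomp(points, center = TRUE, rank. = 3)
  init <- somPlanarInit(points, pca, gridR, gridC)
  fit <- withSeed(seed, {
    ord <- drawOrder()
    som_train_cpp(points, init, gridR, gridC, as.integer(epochs),
                  lr[1], lr[2], radius[1], radius[2], ord, recordError)
  })
  W <- fit$nodes
  # fold check in the PCA parameter plane; restart once from jittered init
  if (somFoldFraction(W, gridR, gridC, pca) > 0.02) {
    warning("grid fold detected; restarting with jittered initialization")
    fit <- withSeed(if (is.null(seed)) NULL else seed + 1L, {
      init2 <- init + matrix(rnorm(length(init), sd = 1e-3 * max(rng)),
                             nrow(init), 3)
      ord <- drawOrder()
      som_train_cpp(points, init2, gridR, gridC, as.integer(epochs),
                    lr[1], lr[2], radius[1], radius[2], ord, recordError)
    })
    W <- fit$nodes
  }
  V <- array(W, c(gridR, gridC, 3))
  if (!is.null(boundary)) {
    V <- somSnapRim(V, boundary)
  } else if (borderCorrection) {
    pitch <- medianSpacing(points)
    V <- somExpandBorder(V, pitch)
  }
  mesh <- quadMesh(V)
  if (recordError) attr(mesh, "epochError") <- fit$epochError
  mesh
}

# planar lattice spanning the two leading principal directions
somPlanarInit <- function(points, pca, gridR, gridC) {
  s1 <- range(pca$x[, 1]); s2 <- range(pca$x[, 2])
  u <- seq(s1[1], s1[2], length.out = gridR)
  v <- seq(s2[1], s2[2], length.out = gridC)
  g <- cbind(rep(u, times = gridC), rep(v, each = gridR))
  sweep(g %*% t(pca$rotation[, 1:2]), 2, pca$center, "+")
}

# fraction of quads with negative signed area in the PCA parameter plane
somFoldFraction <- function(W, gridR, gridC, pca) {
  uv <- sweep(W, 2, pca$center) %*% pca$rotation[, 1:2]
  U <- matrix(uv[, 1], gridR, gridC)
  V <- matrix(uv[, 2], gridR, gridC)
  i <- seq_len(gridR - 1); j <- seq_len(gridC - 1)
  ax <- U[i, j + 1] - U[i, j]; ay <- V[i, j + 1] - V[i, j]
  bx <- U[i + 1, j] - U[i, j]; by <- V[i + 1, j] - V[i, j]
  cr <- ax * by - ay * bx
  s <- sign(sum(sign(cr)))
  if (s == 0) s <- 1
  mean(sign(cr) != s)
}

# snap the grid rim onto the (closed) wound boundary polygon: each rim
# vertex moves to its orthogonal projection on the nearest polygon segment
somSnapRim <- function(V, boundary) {
  r <- dim(V)[1]; c <- dim(V)[2]
  ij <- rbind(
    cbind(seq_len(r), 1), cbind(r, seq(2, c)),
    cbind(seq(r - 1, 1), c), cbind(1, seq(c - 1, 2)))
  A <- boundary
  Bm <- boundary[c(2:nrow(boundary), 1), , drop = FALSE]
  E <- Bm - A
  elen2 <- pmax(rowSums(E^2), 1e-12)
  for (k in seq_len(nrow(ij))) {
    p <- V[ij[k, 1], ij[k, 2], ]
    t <- (sweep(A, 2, p, function(a, b) b - a) * E)
    t <- pmin(pmax(rowSums(t) / elen2, 0), 1)
    proj <- A + E * t
    d2 <- rowSums(sweep(proj, 2, p)^2)
    V[ij[k, 1], ij[k, 2], ] <- proj[which.min(d2), ]
  }
  V
}

# extrapolate border vertices outward by half the local node gap plus half
# the cloud sampling pitch
somExpandBorder <- function(V, pitch) {
  r <- dim(V)[1]; c <- dim(V)[2]
  out <- V
  push <- function(edge, inner) {
    d <- edge - inner                       # n x 3 outward grid direction
    len <- sqrt(rowSums(d^2))
    len[len < 1e-12] <- 1
    edge + 0.5 * d + (0.5 * pitch) * d / len
  }
  out[1, , ]  <- push(matrix(V[1, , ], c, 3),  matrix(V[2, , ], c, 3))
  out[r, , ]  <- push(matrix(V[r, , ], c, 3),  matrix(V[r - 1, , ], c, 3))
  out[, 1, ]  <- push(matrix(out[, 1, ], r, 3),  matrix(out[, 2, ], r, 3))
  out[, c, ]  <- push(matrix(out[, c, ], r, 3),  matrix(out[, c - 1, ], r, 3))
  out
}

#' Quads of a mesh as corner tuples
#'
#' Enumerates the `(r-1)(c-1)` quadrilaterals of the grid in row-major
#' order with consistent winding
#' `(i,j) -> (i+1,j) -> (i+1,j+1) -> (i,j+1)`.
#'
#' @param mesh a [QuadMesh-class].
#' @return Array `nquad x 4 x 3` of quad corner coordinates.
#' @export
meshQuads <- function(mesh) {
  V <- mesh@vertices
  r <- dim(V)[1]; c <- dim(V)[2]
  i <- rep(seq_len(r - 1), times = c - 1)
  j <- rep(seq_len(c - 1), each = r - 1)
  nq <- length(i)
  out <- array(NA_real_, c(nq, 4, 3))
  for (k in 1:3) {
    Vk <- V[, , k]
    out[, 1, k] <- Vk[cbind(i, j)]
    out[, 2, k] <- Vk[cbind(i + 1, j)]
    out[, 3, k] <- Vk[cbind(i + 1, j + 1)]
    out[, 4, k] <- Vk[cbind(i, j + 1)]
  }
  out
}

#' Mean distance from cloud points to their nearest mesh vertex
#'
#' Convenience wrapper used to monitor mesh quality.
#' @param points N x 3 matrix.
#' @param mesh a [QuadMesh-class].
#' @return Mean nearest-vertex distance (mm).
#' @export
meshFitError <- function(points, mesh) {
  mean_nn_dist_cpp(points, meshVertices(mesh))
}

#' Triangles of a quad mesh
#'
#' Splits every quad into two triangles (consistent winding); used for
#' export, volume computation and ray casting.
#' @param mesh a [QuadMesh-class].
#' @return List with `vertices` (matrix (r c) x 3) and `faces`
#'   (ntri x 3 vertex indices, 1-based).
#' @export
meshTriangles <- function(mesh) {
  V <- meshVertices(mesh)
  d <- meshDim(mesh)
  r <- d[1]; c <- d[2]
  id <- function(i, j) i + (j - 1) * r
  i <- rep(seq_len(r - 1), times = c - 1)
  j <- rep(seq_len(c - 1), each = r - 1)
  f1 <- cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1))
  f2 <- cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  list(vertices = V, faces = rbind(f1, f2))
}

#' Ordered boundary ring of a quad mesh
#'
#' Vertices along the outer rim of the grid, counter-clockwise in grid
#' space, without repetition.
#' @param mesh a [QuadMesh-class].
#' @return M x 3 matrix of rim vertices.
#' @export
meshBoundary <- function(mesh) {
  V <- mesh@vertices
  r <- dim(V)[1]; c <- dim(V)[2]
  idx <- rbind(
    cbind(seq_len(r), 1),
    cbind(r, seq(2, c)),
    cbind(seq(r - 1, 1), c),
    cbind(1, seq(c - 1, 2)))
  t(apply(idx, 1, function(ij) V[ij[1], ij[2], ]))
}
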