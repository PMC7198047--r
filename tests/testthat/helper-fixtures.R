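# shared fixtures built in code

# default synthetic stereo rig: 2208 x 1242 sensor, f from the 80 deg
# horizontal field of view, 45 mm baseline
testRig <- function() {
  cam <- pinholeCamera(fx = 2208 / (2 * tan(40 * pi / 180)),
                       fy = 2208 / (2 * tan(40 * pi / 180)),
                       width = 2208, height = 1242)
  stereoRig(cam, baseline = 45)
}

testProjector <- function(offset = c(-50, 0, 0)) {
  projectorModel(pinholeCamera(fx = 900, fy = 900, width = 854, height = 480),
                 R = diag(3), T = -offset)
}

# regular-grid cloud of a height field z = f(x, y) over [-ext, ext]^2,
# returning the same structures the reconstruction produces
gridCloud <- function(f, ext, spacing, noise = 0, seed = NULL) {
  xs <- seq(-ext, ext, by = spacing)
  n <- length(xs)
  g <- expand.grid(x = xs, y = xs)
  z <- f(g$x, g$y)
  if (noise > 0) z <- z + withr::with_seed(seed %||% 1, rnorm(length(z), sd = noise))
  pm <- matrix(seq_len(n * n), n, n, byrow = TRUE)
  list(points = cbind(g$x, g$y, z), pixelMap = pm, x = g$x, y = g$y,
       n = n, spacing = spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# analytic quad mesh of a spherical cap sampled on a polar grid (no
# flat skirt), cavity opening at z = 0, depth positive z
capMesh <- function(r = 10, nth = 64, nph = 64) {
  th <- seq(1e-4, pi / 2, length.out = nth)
  ph <- seq(0, 2 * pi, length.out = nph)
  V <- array(0, c(nth, nph, 3))
  for (j in seq_len(nph)) {
    V[, j, 1] <- r * sin(th) * cos(ph[j])
    V[, j, 2] <- r * sin(th) * sin(ph[j])
    V[, j, 3] <- r * cos(th)    # deepest at the centre, rim at z = 0
  }
  quadMesh(V)
}

# uniform samples on a hemisphere surface (cavity, depth positive)
hemisphereCloud <- function(n, r = 10, seed = 1) {
  withr::with_seed(seed, {
    z <- runif(n, 0, r)           # uniform in z <=> uniform on sphere area
    th <- runif(n, 0, 2 * pi)
    rho <- sqrt(r^2 - z^2)
    cbind(rho * cos(th), rho * sin(th), z)
  })
}
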