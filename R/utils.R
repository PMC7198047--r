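# internal helpers

# run expr with a temporary RNG state seeded by `seed`; NULL leaves the
# current stream untouched
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# median nearest-neighbour spacing of a 2-D or 3-D point set; nearest
# neighbours of a few hundred query points are searched against the full
# cloud in memory-bounded chunks
medianSpacing <- function(pts, maxQuery = 400L) {
  n <- nrow(pts)
  if (n < 2) return(0)
  idx <- if (n > maxQuery) round(seq(1L, n, length.out = maxQuery)) else seq_len(n)
  fullSq <- rowSums(pts^2)
  d2min <- rep(Inf, length(idx))
  chunk <- 100L
  for (s in seq(1L, length(idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(idx))
    block <- pts[idx[s:e], , drop = FALSE]
    d2 <- outer(rowSums(block^2), fullSq, "+") - 2 * block %*% t(pts)
    d2[d2 < 1e-12] <- Inf   # self matches
    d2min[s:e] <- apply(d2, 1, min)
  }
  stats::median(sqrt(pmax(d2min, 0)))
}

rotationMatrix <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

isRotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

# grayscale luminance from an H x W x 3 array in [0,1]
toGray <- function(img) {
  if (length(dim(img)) == 2) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
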