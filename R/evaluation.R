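#' Accuracy as signed percent deviation
#'
#' `(measured - truth) / truth * 100`: the deviation of a measured value
#' from its reference, in percent of the reference.
#'
#' @param measured measured value(s).
#' @param truth reference value(s), nonzero.
#' @return Signed percent deviation (vectorized).
#' @export
accuracyPct <- function(measured, truth) {
  if (any(truth == 0)) stop("true value must be nonzero")
  (measured - truth) / truth * 100
}

#' Coefficient of variation
#'
#' Sample standard deviation over the absolute mean, `sigma / |xbar|` —
#' the precision metric for repeated measurements. Returned as a
#' fraction (multiply by 100 for percent).
#'
#' @param values numeric series, `n >= 2`, nonzero mean.
#' @return CV as a fraction.
#' @export
coefVariation <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined")
  stats::sd(values) / abs(m)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from
#' the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' where MSR/MSC/MSE are the subject, rater and residual mean squares of
#' an `n x k` subjects-by-raters matrix. Raters are treated as a random
#' sample of a population of similar users.
#'
#' @param mat numeric `n x k` matrix, no missing cells.
#' @return ICC(2,1) in \[-1, 1\].
#' @export
icc21 <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters")
  if (anyNA(mat)) stop("no missing cells allowed")
  gm <- mean(mat)
  rm <- rowMeans(mat); cm <- colMeans(mat)
  SSR <- k * sum((rm - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SST <- sum((mat - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (abs(denom) < 1e-300) stop("undefined: zero total variance")
  (MSR - MSE) / denom
}

#' Repeatability coefficient from one-way ANOVA
#'
#' Within-subject standard deviation `s_w` from the residual mean square
#' of a one-way (subjects) ANOVA over replicate measurements, scaled by
#' 2.77 (= 1.96 sqrt(2)): the bound below which the absolute difference
#' of two repeated measurements on the same subject falls for 95% of
#' pairs.
#'
#' @param mat numeric `n x m` matrix: n subjects, m >= 2 replicates.
#' @return Repeatability in the units of the measurement; attribute
#'   `sw` holds the within-subject SD.
#' @export
repeatabilityCoeff <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); m <- ncol(mat)
  if (m < 2) stop("need at least 2 replicates per subject")
  rm <- rowMeans(mat)
  SSW <- sum((mat - rm)^2)
  sw <- sqrt(SSW / (n * (m - 1)))
  out <- 2.77 * sw
  attr(out, "sw") <- sw
  out
}

#' Summarize a rater study
#'
#' Per-parameter accuracy (mean absolute percent deviation over all
#' cells), precision (CV across raters, averaged over phantoms) and
#' inter-rater ICC(2,1).
#'
#' @param study a [RaterStudy-class].
#' @return Data frame with one row per parameter.
#' @export
summarizeStudy <- function(study) {
  M <- study@measurements
  pn <- dimnames(M)[[3]]
  out <- data.frame(parameter = pn,
                    accuracy_pct = NA_real_, cv_pct = NA_real_,
                    icc21 = NA_real_)
  for (p in seq_along(pn)) {
    slice <- M[, , p, drop = FALSE][, , 1]
    truth <- study@truth[, p]
    out$accuracy_pct[p] <- mean(abs(accuracyPct(slice, truth)), na.rm = TRUE)
    out$cv_pct[p] <- 100 * mean(apply(slice, 1, coefVariation), na.rm = TRUE)
    out$icc21[p] <- icc21(slice)
  }
  out
}
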