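# Internal numerical / RNG helpers shared across modules.

#' @importFrom stats rnorm runif quantile var cov sd plogis median
NULL

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so library code never perturbs user RNG.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic sub-stream derivation: changing one stage's stream must not
## reshuffle the others. Keeps results inside 32-bit integer range.
deriveSeed <- function(seed, stream) {
  (as.numeric(seed) * 97 + stream * 13 + 1) %% 2147483587
}

## Half-up rounding (MATLAB-style), used by the order-statistic threshold and
## by metric presentation; base round() is banker's.
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## 32-bit TIFF samples are stored as integers k = trunc(x * (2^32 - 1)) and
## read back as k / 2^32. Band grids are therefore kept on that canonical
## k / 2^32 grid in memory (precision 2^-32, far below any reflectance
## noise), and writing pre-compensates the truncation so the round trip is
## bit-exact.
tiffQuantize <- function(x) {
  floor(x * 4294967295) / 4294967296
}

## Inverse-prepare a canonical-grid value for writeTIFF: recover k and emit
## a value that truncates back to exactly k.
tiffEncode <- function(x) {
  k <- round(x * 4294967296)
  pmin(1, (k + 0.5) / 4294967295)
}

## Symmetric (reflect) index into 1..len for any integer offset, repeating
## the reflection with period 2*len so padding radii may exceed the grid.
reflectIndex <- function(i, len) {
  j <- (i - 1L) %% (2L * len)
  ifelse(j >= len, 2L * len - 1L - j, j) + 1L
}

## Symmetric (reflect) padding of a matrix by r rows/cols on every side.
padReflect <- function(m, r) {
  ri <- reflectIndex((1L - r):(nrow(m) + r), nrow(m))
  ci <- reflectIndex((1L - r):(ncol(m) + r), ncol(m))
  m[ri, ci, drop = FALSE]
}

## Sum over a (2r+1)x(2r+1) moving window with reflect padding, returned at
## the original grid size. Implemented as a sum of shifted copies: O(w^2)
## vectorized adds, fast for the 7x7 windows used here.
boxSum <- function(m, r) {
  mp <- padReflect(m, r)
  n <- nrow(m)
  p <- ncol(m)
  out <- matrix(0, n, p)
  for (dr in 0:(2L * r)) {
    rows <- (1L + dr):(n + dr)
    for (dc in 0:(2L * r)) {
      out <- out + mp[rows, (1L + dc):(p + dc), drop = FALSE]
    }
  }
  out
}

## 1-D Gaussian kernel, truncated at 3 sigma, normalized to sum 1.
gaussianKernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Separable Gaussian smoothing with reflect boundaries.
gaussianSmooth <- function(m, sigma) {
  k <- gaussianKernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  p <- ncol(m)
  mp <- padReflect(m, r)
  tmp <- matrix(0, n, ncol(mp))
  for (a in seq_along(k)) {
    tmp <- tmp + k[a] * mp[(a):(a + n - 1L), , drop = FALSE]
  }
  out <- matrix(0, n, p)
  for (a in seq_along(k)) {
    out <- out + k[a] * tmp[, (a):(a + p - 1L), drop = FALSE]
  }
  out
}

## Squared Euclidean cross-distances between rows of A (n x d) and B (m x d).
crossDistSq <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
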