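#' Fit a one-class PCA detector
#'
#' Eigendecomposes the covariance matrix of the (centred) target-class
#' training data and retains the leading orthonormal eigenvectors: either
#' an explicit component count `nComponents`, or the smallest count whose
#' cumulative eigenvalue share reaches `varianceFraction`. The novelty
#' threshold is the [fractionThreshold()] of the training reconstruction
#' errors at `1 - outlierFraction` (default: 10% of training targets
#' rejected).
#'
#' @param trainTargets a [FeatureTable-class] (standardized upstream) or
#'   numeric matrix of target-class rows.
#' @param varianceFraction retained-variance fraction in (0, 1\]; ignored
#'   when `nComponents` is given.
#' @param nComponents explicit component count, overrides
#'   `varianceFraction`.
#' @param outlierFraction training rejection fraction, default 0.10.
#' @param center centre by the training mean (default `TRUE`).
#' @return a fitted [PcaModel-class].
#' @export
fitOcPca <- function(trainTargets, varianceFraction = 0.95,
                     nComponents = NULL, outlierFraction = 0.10,
                     center = TRUE) {
  x <- featureValues(trainTargets)
  d <- ncol(x)
  if (nrow(x) <= d) stop("need more training rows than feature dimensions")
  if (outlierFraction <= 0 || outlierFraction >= 1) {
    stop("outlierFraction must lie strictly in (0, 1)")
  }
  if (is.null(nComponents) &&
      (varianceFraction <= 0 || varianceFraction > 1)) {
    stop("varianceFraction must lie in (0, 1]")
  }
  mu <- if (center) colMeans(x) else rep(0, d)
  xc <- sweep(x, 2L, mu, "-")
  co <- cov(xc)
  eg <- eigen(co, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev[1L], .Machine$double.eps) * 1e-12)
  if (!is.null(nComponents)) {
    m <- as.integer(nComponents)
    if (m < 1L || m > d) stop("nComponents must lie in 1..", d)
  } else if (varianceFraction >= 1 - 1e-12) {
    m <- d
    if (m > rank) {
      warning("covariance rank ", rank, " caps the component count")
      m <- rank
    }
  } else {
    share <- cumsum(ev) / sum(ev)
    m <- which(share >= varianceFraction - 1e-12)[1L]
    if (m > rank) {
      warning("covariance rank ", rank, " caps the component count")
      m <- rank
    }
  }
  model <- new("PcaModel", center = mu,
               basis = eg$vectors[, seq_len(m), drop = FALSE],
               eigenvalues = ev, nComponents = as.integer(m),
               nFreeParams = d * m, threshold = NA_real_,
               fractionTargets = 1 - outlierFraction,
               standardization = featureStandardization(trainTargets))
  err <- pcaErrors(model, x)
  model@threshold <- fractionThreshold(err, 1 - outlierFraction)
  model
}

#' Squared PCA reconstruction distance
#'
#' `||(z - mean) - W W' (z - mean)||^2`: the squared distance between an
#' object and its projection onto the retained principal subspace. The
#' simplification `W (W' W)^{-1} W' = W W'` holds because the basis is
#' orthonormal.
#'
#' @param model a fitted [PcaModel-class].
#' @param z a feature vector or matrix of rows in the model's coordinates.
#' @return non-negative squared distances.
#' @export
pcaReconstructionError <- function(model, z) {
  stopifnot(is(model, "PcaModel"))
  m <- if (is.matrix(z)) z else matrix(as.numeric(z), nrow = 1L)
  if (ncol(m) != length(model@center)) {
    stop("input dimension ", ncol(m), " does not match the model's ",
         length(model@center))
  }
  pcaErrors(model, m)
}

pcaErrors <- function(model, m) {
  zc <- sweep(m, 2L, model@center, "-")
  proj <- (zc %*% model@basis) %*% t(model@basis)
  pmax(rowSums((zc - proj)^2), 0)
}

#' @describeIn noveltyScores squared PCA subspace reconstruction distance.
#' @export
setMethod("noveltyScores", "PcaModel", function(model, features) {
  pcaErrors(model, modelMatrix(model, features))
})

setMethod("show", "PcaModel", function(object) {
  cat("PcaModel (one-class PCA)\n",
      " components:", object@nComponents, "of", length(object@center),
      sprintf("(%.1f%% variance)",
              100 * sum(object@eigenvalues[seq_len(object@nComponents)]) /
                sum(object@eigenvalues)), "\n",
      " threshold:", if (is.na(object@threshold)) "unset" else
        signif(object@threshold, 6),
      sprintf("(accepts %.0f%% of targets)",
              100 * object@fractionTargets), "\n")
})
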