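#' Order-statistic fraction threshold
#'
#' The shared thresholding rule of all fraction-calibrated detectors: sort
#' the training novelty scores ascending, take `k = round(fraction * n)`
#' (half-up, 1-based), and return the midpoint
#' `(sorted[k] + sorted[k + 1]) / 2`. With distinct scores exactly `k`
#' training points fall at or below the threshold, so the training
#' rejection rate equals `1 - fraction` to within `1/n`.
#'
#' @param distances numeric vector of training novelty scores (length >= 2).
#' @param fraction fraction of targets to accept, in (0, 1).
#' @return the threshold value.
#' @examples
#' fractionThreshold(1:10, 0.8)  # (8 + 9) / 2 = 8.5
#' @export
fractionThreshold <- function(distances, fraction) {
  n <- length(distances)
  if (n < 2L) stop("need at least 2 distances to place a threshold")
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly in (0, 1)")
  }
  k <- roundHalfUp(fraction * n)
  if (k < 1 || k >= n) {
    stop("fraction ", fraction, " is degenerate for ", n,
         " distances (order statistic ", k, " out of range)")
  }
  s <- sort(distances)
  (s[k] + s[k + 1L]) / 2
}

#' Best matching unit of a SOM
#'
#' Exhaustive scan over codebook units for the minimal squared Euclidean
#' distance; ties broken by the lowest unit index.
#'
#' @param model a [SomModel-class].
#' @param x a feature vector.
#' @return list with `unit` (1-based index) and `distanceSq` (the
#'   quantization error).
#' @export
bmuDistance <- function(model, x) {
  stopifnot(is(model, "SomModel"))
  if (length(x) != ncol(model@codebooks)) {
    stop("input dimension ", length(x), " does not match codebooks (",
         ncol(model@codebooks), ")")
  }
  d2 <- colSums((t(model@codebooks) - as.numeric(x))^2)
  unit <- which.min(d2)
  list(unit = unit, distanceSq = d2[unit])
}

#' Train a one-class self-organizing map
#'
#' Standard online Kohonen learning of a rectangular codebook grid on
#' target-class data: per presented sample the best matching unit and its
#' neighbours (Gaussian neighbourhood on the grid) move toward the sample,
#' with the neighbourhood radius and the learning rate decaying
#' exponentially over the run. Codebooks are initialized from a random
#' sample of training rows. The novelty threshold is left unset; calibrate
#' it with [calibrateSom()].
#'
#' @param trainTargets a [FeatureTable-class] (standardized upstream) or
#'   numeric matrix of target-class rows.
#' @param rows,cols grid dimensions, default 8 x 8 rectangular.
#' @param epochs passes over the training data, default 20.
#' @param initialRadius,finalRadius neighbourhood radius schedule; defaults
#'   `max(rows, cols) / 2` down to 0.5.
#' @param initialRate,finalRate learning-rate schedule, defaults 0.5 to 0.01.
#' @param seed integer seed (initialization and presentation order).
#' @return a [SomModel-class] with `threshold = NA` until calibrated.
#' @export
fitOcSom <- function(trainTargets, rows = 8L, cols = 8L, epochs = 20L,
                     initialRadius = max(rows, cols) / 2, finalRadius = 0.5,
                     initialRate = 0.5, finalRate = 0.01, seed = 1L) {
  x <- featureValues(trainTargets)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("grid dimensions must be >= 1")
  if (epochs < 1L) stop("training needs at least one epoch")
  n <- nrow(x)
  units <- rows * cols
  if (n < units) {
    warning("fewer training samples (", n, ") than SOM units (", units, ")")
  }
  grid <- cbind(row = rep(seq_len(rows), times = cols),
                col = rep(seq_len(cols), each = rows))
  codebooks <- withSeed(deriveSeed(seed, 3L), {
    x[sample.int(n, units, replace = n < units), , drop = FALSE]
  })
  order <- withSeed(deriveSeed(seed, 4L), {
    unlist(lapply(seq_len(epochs), function(e) sample.int(n)))
  })
  steps <- length(order)
  denom <- max(steps - 1L, 1L)
  for (s in seq_len(steps)) {
    frac <- (s - 1) / denom
    radius <- initialRadius * (finalRadius / initialRadius)^frac
    rate <- initialRate * (finalRate / initialRate)^frac
    xi <- x[order[s], ]
    diff <- sweep(codebooks, 2L, xi, "-")
    bmu <- which.min(rowSums(diff^2))
    gridD2 <- (grid[, 1L] - grid[bmu, 1L])^2 + (grid[, 2L] - grid[bmu, 2L])^2
    h <- exp(-gridD2 / (2 * radius^2))
    codebooks <- codebooks - (rate * h) * diff
  }
  new("SomModel", codebooks = codebooks, gridRows = rows, gridCols = cols,
      gridCoords = grid, threshold = NA_real_, fractionTargets = NA_real_,
      standardization = featureStandardization(trainTargets))
}

#' Calibrate the SOM novelty threshold
#'
#' Sets the threshold at the [fractionThreshold()] of the training
#' quantization errors (BMU distances) so that `fractionTargets` of the
#' training targets fall at or below it. The default 0.95 realizes a 5%
#' outlier-acceptance rate.
#'
#' @param model a trained [SomModel-class].
#' @param trainTargets the training data used to fit it (same coordinates).
#' @param fractionTargets fraction of training targets accepted, in (0, 1).
#' @return the model with its threshold set.
#' @export
calibrateSom <- function(model, trainTargets, fractionTargets = 0.95) {
  stopifnot(is(model, "SomModel"))
  x <- featureValues(trainTargets)
  d <- somQuantizationError(model, x)
  model@threshold <- fractionThreshold(d, fractionTargets)
  model@fractionTargets <- fractionTargets
  model
}

## Vectorized quantization error (min squared distance to any codebook)
## for a matrix already in model coordinates.
somQuantizationError <- function(model, m) {
  scoreBlocked(m, 50000L, function(block) {
    d2 <- crossDistSq(block, model@codebooks)
    d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
  })
}

#' @describeIn noveltyScores SOM quantization error (squared distance to the
#'   best matching unit).
#' @export
setMethod("noveltyScores", "SomModel", function(model, features) {
  somQuantizationError(model, modelMatrix(model, features))
})

setMethod("show", "SomModel", function(object) {
  cat("SomModel (one-class SOM)\n",
      " grid:", object@gridRows, "x", object@gridCols, "rectangular\n",
      " threshold:", if (is.na(object@threshold)) "unset" else
        signif(object@threshold, 6),
      if (!is.na(object@fractionTargets)) {
        paste0("(accepts ", object@fractionTargets * 100, "% of targets)")
      } else "", "\n")
})
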