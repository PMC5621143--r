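#' Local-variance texture band
#'
#' Per-pixel population variance of band values in a square moving window
#' (default 7 x 7), the standard local-variance texture operator for
#' discriminating rough target-weed canopy from smooth graminaceous
#' background. Edges are handled by reflect padding; nodata pixels are
#' excluded from every window statistic and the output is `NA` only where a
#' whole window is nodata.
#'
#' @param band numeric matrix of reflectances; `NA` marks nodata.
#' @param window odd window side length, >= 3.
#' @param nodataMask optional logical matrix; combined with `NA`s in `band`.
#' @return matrix of the same dimension holding window variances.
#' @examples
#' b <- matrix(rnorm(100), 10, 10)
#' v <- localVariance(b, window = 7)
#' @export
localVariance <- function(band, window = 7L, nodataMask = NULL) {
  if (length(window) != 1L || window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3, got ", window)
  }
  valid <- !is.na(band)
  if (!is.null(nodataMask)) valid <- valid & !nodataMask
  if (any(!is.finite(band[valid]))) {
    stop("band holds non-finite values outside the nodata mask")
  }
  r <- (as.integer(window) - 1L) %/% 2L
  ## shift by the global mean: variance is shift-invariant and this kills
  ## the catastrophic cancellation of E[x^2] - E[x]^2 on flat regions
  x <- band - mean(band[valid])
  x[!valid] <- 0
  s1 <- boxSum(x, r)
  s2 <- boxSum(x^2, r)
  cnt <- boxSum(valid + 0, r)
  mu <- s1 / cnt
  v <- s2 / cnt - mu^2
  v[cnt == 0] <- NA_real_
  v[!is.na(v) & v < 0] <- 0   # guard tiny negative rounding
  v
}

#' Assemble per-pixel feature vectors
#'
#' Builds the N x 4 feature matrix (green, red, NIR, local-variance texture
#' of the NIR band) in raster scan order (row by row), dropping nodata
#' pixels; class labels are attached when a label raster is supplied (its
#' code-0 pixels are dropped too).
#'
#' @param scene a [MultibandScene-class].
#' @param labels optional [LabelRaster-class] of matching dimension.
#' @param window texture window side length (odd, default 7).
#' @return a [FeatureTable-class].
#' @export
assembleFeatures <- function(scene, labels = NULL, window = 7L) {
  stopifnot(is(scene, "MultibandScene"))
  d <- dim(scene@green)
  if (!is.null(labels)) {
    stopifnot(is(labels, "LabelRaster"))
    if (!identical(dim(labels@labels), d)) {
      stop("label raster dimensions do not match the scene")
    }
  }
  texture <- localVariance(scene@nir, window = window,
                           nodataMask = scene@nodataMask)
  ## raster scan order: row-major enumeration of the grid
  idx <- cbind(row = rep(seq_len(d[1L]), each = d[2L]),
               col = rep(seq_len(d[2L]), times = d[1L]))
  keep <- !scene@nodataMask[idx] & !is.na(texture[idx])
  lab <- integer(0)
  if (!is.null(labels)) {
    labVec <- labels@labels[idx]
    keep <- keep & labVec != 0L
    lab <- labVec[keep]
  }
  idx <- idx[keep, , drop = FALSE]
  values <- cbind(green = scene@green[idx], red = scene@red[idx],
                  nir = scene@nir[idx], texture = texture[idx])
  new("FeatureTable", values = values, labels = lab,
      pixelIndex = idx, standardization = list())
}

#' Balanced calibration sample
#'
#' Draws exactly `perClass` rows per class (codes 1 and 2) without
#' replacement; the default matches the balanced two-class calibration
#' protocol of 1434 pixels per class (2868 pixels total). Deterministic
#' given `seed`.
#'
#' @param table a labelled [FeatureTable-class].
#' @param perClass rows to draw from each class.
#' @param seed integer seed.
#' @return a [FeatureTable-class] with `2 * perClass` rows.
#' @export
balancedSample <- function(table, perClass = 1434L, seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  if (!length(table@labels)) stop("balanced sampling needs a labelled table")
  perClass <- as.integer(perClass)
  sel <- withSeed(seed, {
    unlist(lapply(c(1L, 2L), function(cls) {
      rows <- which(table@labels == cls)
      if (length(rows) < perClass) {
        stop("class ", cls, " has only ", length(rows),
             " pixels but ", perClass, " were requested")
      }
      if (perClass == 0L) integer(0) else rows[sample.int(length(rows), perClass)]
    }))
  })
  subsetFeatureTable(table, sel)
}

#' Stratified train/test split
#'
#' Splits a labelled feature table into training and test parts, drawing
#' `round(trainFraction * n_c)` rows (half-up) from each class `c` so that
#' the balanced 2 x 1434 calibration sample at fraction 0.70 yields exactly
#' 1004 + 1004 = 2008 training and 860 test rows. The test part is
#' guaranteed non-empty. Deterministic given `seed`.
#'
#' @param table a labelled [FeatureTable-class].
#' @param trainFraction fraction in (0, 1), default 0.70.
#' @param seed integer seed.
#' @return list with [FeatureTable-class] elements `train` and `test`.
#' @export
splitFeatures <- function(table, trainFraction = 0.70, seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  if (!length(table@labels)) stop("splitting needs a labelled table")
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must lie strictly in (0, 1)")
  }
  trainSel <- withSeed(deriveSeed(seed, 2L), {
    unlist(lapply(c(1L, 2L), function(cls) {
      rows <- which(table@labels == cls)
      nTrain <- max(0L, min(roundHalfUp(trainFraction * length(rows)),
                            length(rows) - 1L))
      rows[sample.int(length(rows), nTrain)]
    }))
  })
  trainSel <- sort(trainSel)
  testSel <- setdiff(seq_along(table@labels), trainSel)
  if (!length(testSel)) stop("split left an empty test set")
  list(train = subsetFeatureTable(table, trainSel),
       test = subsetFeatureTable(table, testSel))
}

#' Feature standardization from target-class training rows
#'
#' `standardizeFeatures` computes per-feature (mean, sd) over the
#' target-class training rows; `applyStandardization` applies the resulting
#' affine map to any table. All detectors are fitted and applied in these
#' standardized coordinates: the RBF spread and the fraction thresholds are
#' scale-sensitive, and the map is recorded in every model so whole-scene
#' classification reuses the training-time coordinates.
#'
#' @param trainTargets a [FeatureTable-class] of target-class training rows.
#' @return a list with numeric length-4 elements `center` and `scale`.
#' @export
standardizeFeatures <- function(trainTargets) {
  stopifnot(is(trainTargets, "FeatureTable"))
  v <- trainTargets@values
  center <- colMeans(v)
  scale <- apply(v, 2L, sd)
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    bad <- colnames(v)[!is.finite(scale) | scale <= 0]
    stop("feature(s) with zero spread cannot be standardized: ",
         paste(bad, collapse = ", "))
  }
  list(center = center, scale = scale)
}

#' @rdname standardizeFeatures
#' @param table a [FeatureTable-class] to transform.
#' @param standardization a map from `standardizeFeatures`.
#' @export
applyStandardization <- function(table, standardization) {
  stopifnot(is(table, "FeatureTable"))
  v <- sweep(sweep(table@values, 2L, standardization$center, "-"),
             2L, standardization$scale, "/")
  new("FeatureTable", values = v, labels = table@labels,
      pixelIndex = table@pixelIndex, standardization = standardization)
}

## Row subset preserving labels, coordinates and standardization.
subsetFeatureTable <- function(table, rows) {
  new("FeatureTable",
      values = table@values[rows, , drop = FALSE],
      labels = if (length(table@labels)) table@labels[rows] else integer(0),
      pixelIndex = table@pixelIndex[rows, , drop = FALSE],
      standardization = table@standardization)
}

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@values), "pixels x",
      ncol(object@values), "features",
      if (length(object@labels)) {
        sprintf("| target %d, other %d", sum(object@labels == 1L),
                sum(object@labels == 2L))
      } else {
        "| unlabelled"
      },
      if (length(object@standardization)) "| standardized" else "", "\n")
})

#' @describeIn FeatureTable-class number of rows and feature columns.
#' @param x a `FeatureTable`.
#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))
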