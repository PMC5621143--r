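#' @import methods
NULL

#' Scene simulation configuration
#'
#' Parameters controlling the synthetic multispectral scene generator: scene
#' geometry, per-class mean reflectance in the green/red/NIR bands, the
#' smooth within-class variability, the per-class high-frequency texture
#' noise, and the spatial structure of the target-weed patches.
#'
#' The target class must have strictly larger `textureAmplitude` than the
#' background: the target weed forms large individuals with rough, uneven
#' canopy texture whereas the graminaceous background is spectrally similar
#' but very smooth, and the local-variance texture band is what encodes that
#' contrast.
#'
#' @slot width,height scene dimensions in pixels.
#' @slot pixelSize ground size of one pixel in metres (default 0.5 m).
#' @slot classSpectra 2 x 3 matrix of mean reflectance, rows `target`/`other`,
#'   columns `green`/`red`/`nir`, values in \[0, 1\].
#' @slot classSpread 2 x 3 matrix of smooth-field standard deviations per
#'   class and band.
#' @slot textureAmplitude length-2 numeric, per-class standard deviation of
#'   the high-frequency (pixel-scale) noise; `target` entry strictly larger.
#' @slot patchCoverage target fraction of the scene covered by weed patches,
#'   in (0, 1).
#' @slot patchScale Gaussian smoothing length (pixels) of the patch-shape
#'   field; larger values give larger, smoother patches.
#' @slot fieldScale smoothing length (pixels) of the within-class reflectance
#'   fields.
#' @slot seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @seealso [sceneConfig()], [generatePatchMask()], [renderScene()]
#' @export
setClass("SceneConfig", representation(
  width = "integer", height = "integer", pixelSize = "numeric",
  classSpectra = "matrix", classSpread = "matrix",
  textureAmplitude = "numeric", patchCoverage = "numeric",
  patchScale = "numeric", fieldScale = "numeric", seed = "integer"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@width < 1L || object@height < 1L) {
    msg <- c(msg, "scene dimensions must be positive")
  }
  if (!all(dim(object@classSpectra) == c(2L, 3L))) {
    msg <- c(msg, "classSpectra must be a 2 x 3 matrix (target/other x green/red/nir)")
  } else if (any(object@classSpectra < 0) || any(object@classSpectra > 1)) {
    msg <- c(msg, "mean reflectances must lie in [0, 1]")
  }
  if (!all(dim(object@classSpread) == c(2L, 3L)) || any(object@classSpread < 0)) {
    msg <- c(msg, "classSpread must be a non-negative 2 x 3 matrix")
  }
  if (length(object@textureAmplitude) != 2L || any(object@textureAmplitude < 0)) {
    msg <- c(msg, "textureAmplitude must be two non-negative values")
  } else if (object@textureAmplitude[1L] <= object@textureAmplitude[2L]) {
    msg <- c(msg, "target textureAmplitude must exceed the background's")
  }
  if (object@patchCoverage <= 0 || object@patchCoverage >= 1) {
    msg <- c(msg, "patchCoverage must lie strictly in (0, 1)")
  }
  if (object@patchScale < 1) msg <- c(msg, "patchScale must be >= 1 pixel")
  if (length(msg)) msg else TRUE
})

#' Multiband reflectance scene
#'
#' A green/red/NIR reflectance raster: three band matrices of identical
#' dimension with values in \[0, 1\], a logical nodata mask, and the ground
#' pixel size. Nodata pixels hold `NA` in the band matrices and are excluded
#' from all downstream statistics.
#'
#' @slot green,red,nir reflectance matrices (rows x cols).
#' @slot nodataMask logical matrix, `TRUE` where no observation exists.
#' @slot pixelSize ground sampling distance in metres.
#' @seealso [renderScene()], [readScene()], [writeScene()]
#' @export
setClass("MultibandScene", representation(
  green = "matrix", red = "matrix", nir = "matrix",
  nodataMask = "matrix", pixelSize = "numeric"
))

setValidity("MultibandScene", function(object) {
  d <- dim(object@green)
  if (!identical(d, dim(object@red)) || !identical(d, dim(object@nir)) ||
      !identical(d, dim(object@nodataMask))) {
    return("all bands and the nodata mask must share identical dimensions")
  }
  if (!is.logical(object@nodataMask)) return("nodataMask must be logical")
  ok <- !object@nodataMask
  for (b in list(object@green, object@red, object@nir)) {
    v <- b[ok]
    if (anyNA(v) || any(v < 0 | v > 1)) {
      return("valid pixels must hold finite reflectance in [0, 1]")
    }
  }
  TRUE
})

#' Per-pixel class label raster
#'
#' Integer codes per pixel: 1 = target weed, 2 = other vegetation,
#' 0 = nodata.
#'
#' @slot labels integer matrix with codes in \{0, 1, 2\}.
#' @export
setClass("LabelRaster", representation(labels = "matrix"))

setValidity("LabelRaster", function(object) {
  if (!is.integer(object@labels)) return("labels must be an integer matrix")
  if (!all(object@labels %in% c(0L, 1L, 2L))) {
    return("label codes limited to 0 (nodata), 1 (target), 2 (other)")
  }
  TRUE
})

#' Per-pixel feature table
#'
#' N x 4 matrix of (green, red, NIR, texture) feature vectors in raster scan
#' order, with the originating pixel coordinates, optional class labels, and
#' (once standardized) the affine standardization map that was applied.
#'
#' @slot values numeric N x 4 matrix, columns `green`, `red`, `nir`, `texture`.
#' @slot labels integer vector of length N (codes 1/2) or length 0 when
#'   unlabelled.
#' @slot pixelIndex integer N x 2 matrix of (row, col), 1-based.
#' @slot standardization list with elements `center` and `scale` (length-4
#'   numerics computed from target-class training rows) once
#'   [applyStandardization()] has been applied; empty list otherwise.
#' @export
setClass("FeatureTable", representation(
  values = "matrix", labels = "integer", pixelIndex = "matrix",
  standardization = "list"
))

setValidity("FeatureTable", function(object) {
  n <- nrow(object@values)
  if (ncol(object@values) != 4L) return("feature table must have 4 columns")
  if (length(object@labels) && length(object@labels) != n) {
    return("labels length must match row count")
  }
  if (length(object@labels) && !all(object@labels %in% c(1L, 2L))) {
    return("feature-table labels must be 1 (target) or 2 (other)")
  }
  if (nrow(object@pixelIndex) != n || ncol(object@pixelIndex) != 2L) {
    return("pixelIndex must be an N x 2 matrix")
  }
  if (anyNA(object@values)) return("feature rows must be free of nodata")
  s <- object@standardization
  if (length(s) && (!all(c("center", "scale") %in% names(s)) ||
                    any(s$scale <= 0))) {
    return("standardization needs positive scale and a center")
  }
  TRUE
})

#' One-class detector models
#'
#' `OneClassModel` is the virtual parent of the four fitted detectors. All
#' share the same contract: [noveltyScores()] maps feature vectors to a
#' non-negative novelty score, and [classifyFeatures()] assigns code 1
#' (target) where score <= threshold and code 2 (novel / other vegetation)
#' where score > threshold. The threshold is an order-statistic midpoint of
#' the training-target scores chosen so that a configured fraction of
#' training targets falls inside (see [fractionThreshold()]).
#'
#' @slot threshold decision cut on the novelty score.
#' @slot fractionTargets fraction of training targets accepted by the
#'   calibrated threshold.
#' @slot standardization the feature standardization map (computed from
#'   target-class training rows) under which the model was fitted.
#' @export
setClass("OneClassModel", representation(
  "VIRTUAL",
  threshold = "numeric", fractionTargets = "numeric", standardization = "list"
))

#' @describeIn OneClassModel-class Support Vector Data Description: minimal
#'   enclosing hypersphere of the target class in RBF feature space. Scores
#'   are squared kernel distances to the sphere centre.
#' @slot supportPoints M x 4 matrix of support vectors (standardized).
#' @slot alphas dual coefficients of the support vectors.
#' @slot sigma RBF spread.
#' @slot C box constraint, `1 / (N * nu)`.
#' @slot offset cached constant `sum_ij alpha_i alpha_j K(x_i, x_j)`.
#' @slot boundaryRadiusSq radius read off boundary support vectors
#'   (0 < alpha < C), logged for comparison with the calibrated threshold.
#' @slot nTrain,nu training size and outlier-fraction bound.
#' @export
setClass("SvddModel", contains = "OneClassModel", representation(
  supportPoints = "matrix", alphas = "numeric", sigma = "numeric",
  C = "numeric", offset = "numeric", boundaryRadiusSq = "numeric",
  nTrain = "integer", nu = "numeric"
))

#' @describeIn OneClassModel-class One-class self-organizing map: rectangular
#'   codebook grid trained on target data; the score of a vector is its
#'   quantization error (squared distance to the best matching unit).
#' @slot codebooks (rows*cols) x 4 weight matrix.
#' @slot gridRows,gridCols SOM grid dimensions.
#' @slot gridCoords unit coordinates on the grid, (rows*cols) x 2.
#' @export
setClass("SomModel", contains = "OneClassModel", representation(
  codebooks = "matrix", gridRows = "integer", gridCols = "integer",
  gridCoords = "matrix"
))

#' @describeIn OneClassModel-class Single-hidden-layer autoencoder (sigmoid
#'   hidden units, linear output) trained to reproduce target feature
#'   vectors; the score is the squared reconstruction error.
#' @slot W1,b1 encoder weights (4 x hidden) and biases.
#' @slot W2,b2 decoder weights (hidden x 4) and biases.
#' @slot lossTrace mean squared reconstruction error per epoch.
#' @export
setClass("AeModel", contains = "OneClassModel", representation(
  W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
  lossTrace = "numeric"
))

#' @describeIn OneClassModel-class One-class PCA: orthonormal principal
#'   subspace of the target class; the score is the squared reconstruction
#'   distance to the subspace.
#' @slot center training-target mean (zero vector when uncentred).
#' @slot basis d x M orthonormal basis of the retained subspace.
#' @slot eigenvalues all covariance eigenvalues, descending.
#' @slot nComponents retained component count M.
#' @slot nFreeParams d*M, recorded as metadata only.
#' @export
setClass("PcaModel", contains = "OneClassModel", representation(
  center = "numeric", basis = "matrix", eigenvalues = "numeric",
  nComponents = "integer", nFreeParams = "numeric"
))

#' Confusion table for two-class accuracy assessment
#'
#' 2 x 2 actual-vs-predicted pixel counts; rows are the actual class
#' (target, other), columns the predicted class.
#'
#' @slot counts 2 x 2 integer matrix.
#' @seealso [confusionTable()], [accuracyMetrics()]
#' @export
setClass("ConfusionTable", representation(counts = "matrix"))

setValidity("ConfusionTable", function(object) {
  ct <- object@counts
  if (!all(dim(ct) == c(2L, 2L))) return("counts must be 2 x 2")
  if (any(ct < 0) || any(ct != round(ct))) {
    return("counts must be non-negative integers")
  }
  TRUE
})
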