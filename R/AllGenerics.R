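#' Novelty scores of feature vectors under a fitted detector
#'
#' Maps each feature vector to the detector's non-negative novelty score:
#' squared kernel distance to the sphere centre (SVDD), quantization error
#' (SOM), squared reconstruction error (autoencoder), or squared subspace
#' reconstruction distance (PCA).
#'
#' Features are standardized with the model's stored map before scoring. A
#' [FeatureTable-class] that already carries a standardization map must carry
#' the *same* map the model was fitted under, otherwise an error is raised;
#' raw (unstandardized) tables and plain matrices are standardized on the
#' fly.
#'
#' @param model a fitted [OneClassModel-class].
#' @param features a [FeatureTable-class] or numeric matrix with 4 columns.
#' @return numeric vector of scores, one per row.
#' @export
setGeneric("noveltyScores", function(model, features) {
  standardGeneric("noveltyScores")
})

#' Classify feature vectors with a fitted one-class detector
#'
#' Applies the detector's calibrated decision rule: code 1 (target) where
#' the novelty score is less than or equal to the threshold, code 2 (other
#' vegetation / novel) where it exceeds it. The threshold point itself is a
#' target on every detector.
#'
#' @inheritParams noveltyScores
#' @return integer vector of codes in \{1, 2\}.
#' @export
setGeneric("classifyFeatures", function(model, features) {
  standardGeneric("classifyFeatures")
})

#' @describeIn noveltyScores score then threshold; shared by all detectors.
#' @export
setMethod("classifyFeatures", "OneClassModel", function(model, features) {
  if (!length(model@threshold) || is.na(model@threshold)) {
    stop("model has no calibrated threshold; fit and calibrate it first")
  }
  s <- noveltyScores(model, features)
  ifelse(s <= model@threshold, 1L, 2L)
})

## Resolve a FeatureTable / matrix into the standardized coordinates the
## model was fitted in.
modelMatrix <- function(model, features) {
  std <- model@standardization
  if (is(features, "FeatureTable")) {
    if (length(features@standardization)) {
      if (length(std) &&
          (!isTRUE(all.equal(unname(std$center),
                             unname(features@standardization$center),
                             tolerance = 1e-12)) ||
           !isTRUE(all.equal(unname(std$scale),
                             unname(features@standardization$scale),
                             tolerance = 1e-12)))) {
        stop("feature table was standardized with a different map than the model")
      }
      return(features@values)
    }
    m <- features@values
  } else if (is.matrix(features)) {
    m <- features
  } else {
    m <- matrix(as.numeric(features), nrow = 1L)
  }
  if (length(std)) {
    if (ncol(m) != length(std$center)) {
      stop("feature dimension ", ncol(m), " does not match the model's ",
           length(std$center))
    }
    m <- sweep(sweep(m, 2L, std$center, "-"), 2L, std$scale, "/")
  }
  m
}
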