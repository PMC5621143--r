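#' Train a one-class detector end to end
#'
#' The full calibration protocol over a labelled scene: assemble per-pixel
#' features (spectral bands + NIR local-variance texture), draw the
#' balanced two-class calibration sample, split it 70/30 stratified by
#' class, standardize by the *target-class training rows*, and fit the
#' chosen detector on those target training rows only — the "other" class
#' never reaches the detector (one-class discipline); it is used solely for
#' accuracy assessment on the held-out split.
#'
#' @param scene a [MultibandScene-class].
#' @param labels a [LabelRaster-class] of ground truth.
#' @param detector one of `"ocsvm"`, `"ocsom"`, `"autoencoder"`, `"ocpca"`.
#' @param perClass balanced-sample size per class, default 1434.
#' @param trainFraction training fraction of the split, default 0.70.
#' @param seed integer seed driving sampling, splitting and detector
#'   initialization.
#' @param detectorArgs named list of extra arguments passed to the
#'   detector's fit function (e.g. `list(sigma = 2.5, nu = 0.05)`).
#' @return list with elements `model` (a fitted [OneClassModel-class]),
#'   `train`/`test` (standardized [FeatureTable-class]s), and `report`
#'   (sample sizes and the training rejection rate).
#' @examples
#' sim <- simulateScene(sceneConfig(width = 96, height = 96, seed = 7))
#' fit <- runTraining(sim$scene, sim$labels, "ocpca", perClass = 300,
#'                    seed = 7)
#' fit$report$trainRejectionRate
#' @export
runTraining <- function(scene, labels, detector = c("ocsvm", "ocsom",
                                                    "autoencoder", "ocpca"),
                        perClass = 1434L, trainFraction = 0.70, seed = 1L,
                        detectorArgs = list()) {
  detector <- match.arg(detector)
  table <- assembleFeatures(scene, labels)
  sample <- balancedSample(table, perClass = perClass,
                           seed = deriveSeed(seed, 6L))
  parts <- splitFeatures(sample, trainFraction = trainFraction, seed = seed)
  trainTargets <- subsetFeatureTable(parts$train,
                                     which(parts$train@labels == 1L))
  std <- standardizeFeatures(trainTargets)
  trainStd <- applyStandardization(parts$train, std)
  testStd <- applyStandardization(parts$test, std)
  targetsStd <- subsetFeatureTable(trainStd, which(trainStd@labels == 1L))
  model <- fitDetector(detector, targetsStd, seed, detectorArgs)
  trainCodes <- classifyFeatures(model, targetsStd)
  report <- list(
    detector = detector, seed = seed,
    pixelsAvailable = nrow(table@values),
    sampleSize = nrow(sample@values),
    trainSize = nrow(parts$train@values),
    testSize = nrow(parts$test@values),
    trainTargetSize = nrow(targetsStd@values),
    trainRejectionRate = mean(trainCodes == 2L))
  list(model = model, train = trainStd, test = testStd, report = report)
}

## Dispatch a detector fit with seeded defaults; detectorArgs override.
fitDetector <- function(detector, targetsStd, seed, detectorArgs) {
  fitSeed <- deriveSeed(seed, 7L)
  switch(detector,
    ocsvm = do.call(fitSvdd, c(list(trainTargets = targetsStd), detectorArgs)),
    ocsom = {
      args <- c(list(trainTargets = targetsStd, seed = fitSeed), detectorArgs)
      fraction <- if (is.null(args$fractionTargets)) 0.95 else args$fractionTargets
      args$fractionTargets <- NULL
      calibrateSom(do.call(fitOcSom, args), targetsStd, fraction)
    },
    autoencoder = do.call(fitAutoencoder,
                          c(list(trainTargets = targetsStd, seed = fitSeed),
                            detectorArgs)),
    ocpca = do.call(fitOcPca, c(list(trainTargets = targetsStd),
                                detectorArgs)))
}

#' Classify a whole scene
#'
#' Scores every valid pixel with the fitted detector and writes codes 1
#' (target weed) / 2 (other vegetation) into a label raster, 0 at nodata.
#' Scoring is blocked over pixel rows so mosaics of ~10^6 pixels fit in
#' modest memory.
#'
#' @param model a fitted [OneClassModel-class].
#' @param scene a [MultibandScene-class].
#' @param window texture window used at training time (default 7).
#' @return a [LabelRaster-class] prediction map.
#' @export
classifyScene <- function(model, scene, window = 7L) {
  stopifnot(is(model, "OneClassModel"), is(scene, "MultibandScene"))
  table <- assembleFeatures(scene, window = window)
  out <- matrix(0L, nrow(scene@green), ncol(scene@green))
  if (nrow(table@values)) {
    out[table@pixelIndex] <- classifyFeatures(model, table)
  }
  new("LabelRaster", labels = out)
}

#' Evaluate a prediction map against ground truth
#'
#' Compares predicted and actual codes over labelled pixels. When
#' `testIndex` (an N x 2 matrix of pixel coordinates, typically the
#' held-out split's `pixelIndex`) is supplied, evaluation is restricted to
#' those pixels, reproducing the held-out-sample validation protocol;
#' otherwise all pixels labelled in both rasters are scored.
#'
#' @param predicted,truth [LabelRaster-class]s of identical dimension.
#' @param testIndex optional integer matrix of (row, col) pixels.
#' @return list with `confusion` (a [ConfusionTable-class]) and `metrics`
#'   (see [accuracyMetrics()]).
#' @export
runEvaluate <- function(predicted, truth, testIndex = NULL) {
  stopifnot(is(predicted, "LabelRaster"), is(truth, "LabelRaster"))
  if (!identical(dim(predicted@labels), dim(truth@labels))) {
    stop("predicted and truth raster dimensions differ")
  }
  if (is.null(testIndex)) {
    keep <- truth@labels != 0L & predicted@labels != 0L
    actual <- truth@labels[keep]
    pred <- predicted@labels[keep]
  } else {
    actual <- truth@labels[testIndex]
    pred <- predicted@labels[testIndex]
    ok <- actual != 0L & pred != 0L
    actual <- actual[ok]
    pred <- pred[ok]
  }
  ct <- confusionTable(actual, pred)
  list(confusion = ct, metrics = accuracyMetrics(ct))
}

#' Benchmark all four detectors on one scene
#'
#' Runs the full train/classify/evaluate protocol for each detector on the
#' same scene and split, and returns a contingency-style report: one row
#' per detector with overall, user's and producer's accuracies on the
#' held-out test pixels.
#'
#' @param scene a [MultibandScene-class].
#' @param labels a [LabelRaster-class].
#' @param detectors detectors to run, default all four.
#' @param perClass,trainFraction,seed as in [runTraining()].
#' @return list with `summary` (data frame, percentages rounded to 2
#'   decimals) and `fits` (per-detector training output plus evaluation).
#' @export
runBenchmark <- function(scene, labels,
                         detectors = c("ocsvm", "ocsom", "autoencoder",
                                       "ocpca"),
                         perClass = 1434L, trainFraction = 0.70, seed = 1L) {
  fits <- lapply(detectors, function(det) {
    fit <- runTraining(scene, labels, det, perClass = perClass,
                       trainFraction = trainFraction, seed = seed)
    codes <- classifyFeatures(fit$model, fit$test)
    ct <- confusionTable(fit$test@labels, codes)
    fit$evaluation <- list(confusion = ct, metrics = accuracyMetrics(ct))
    fit
  })
  names(fits) <- detectors
  summary <- do.call(rbind, lapply(detectors, function(det) {
    m <- formatMetrics(fits[[det]]$evaluation$metrics)
    data.frame(detector = det, overall = m$overall,
               usersTarget = m$users[["target"]],
               usersOther = m$users[["other"]],
               producersTarget = m$producers[["target"]],
               producersOther = m$producers[["other"]],
               trainRejection = roundHalfUp(
                 100 * fits[[det]]$report$trainRejectionRate, 2L))
  }))
  list(summary = summary, fits = fits)
}

#' Write / read a fitted detector as versioned JSON
#'
#' Serializes any [OneClassModel-class] (class name, package version, and
#' every slot, matrices with their dimensions) to a JSON file at full
#' numeric precision, so identical configurations produce byte-identical
#' model files and the round trip is exact.
#'
#' @param model a fitted [OneClassModel-class].
#' @param path output file.
#' @return `writeModel` returns `path` invisibly; `readModel` the restored
#'   model.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "OneClassModel"))
  slots <- slotNames(class(model))
  payload <- lapply(slots, function(s) encodeSlot(slot(model, s)))
  names(payload) <- slots
  obj <- list(format = "weednov-model", version = 1L,
              class = as.character(class(model)), slots = payload)
  ## 17 significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "weednov-model")) {
    stop("'", path, "' is not a weednov model file")
  }
  model <- new(obj$class)
  for (s in names(obj$slots)) {  # slot-wise: `C =` would clash with new()'s Class
    slot(model, s) <- decodeSlot(obj$slots[[s]])
  }
  model
}

encodeSlot <- function(v) {
  if (is.matrix(v)) {
    list(type = "matrix", dim = dim(v), data = as.vector(v))
  } else if (is.list(v)) {
    list(type = "list", data = lapply(v, encodeSlot))
  } else {
    list(type = typeof(v), data = v)
  }
}

decodeSlot <- function(e) {
  if (identical(e$type, "matrix")) {
    matrix(if (is.null(e$data)) numeric(0) else as.numeric(e$data),
           nrow = e$dim[1L], ncol = e$dim[2L])
  } else if (identical(e$type, "list")) {
    lapply(e$data, decodeSlot)
  } else if (identical(e$type, "integer")) {
    as.integer(e$data)
  } else if (identical(e$type, "double")) {
    v <- e$data
    if (is.null(v)) NA_real_ else as.numeric(v)
  } else {
    e$data
  }
}
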