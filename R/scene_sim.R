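#' Build a scene simulation configuration
#'
#' The defaults emulate a 0.5 m resolution green/red/NIR orthomosaic of a
#' weedy grassland: a smooth-textured background vegetation class and
#' spatially contiguous target-weed patches whose reflectance overlaps the
#' background strongly in the visible bands and partially in the NIR, but
#' whose canopy texture (pixel-scale reflectance roughness) is an order of
#' magnitude higher. The default spectra are synthetic — chosen to reproduce
#' that qualitative pattern, not field-measured values.
#'
#' @param width,height scene size in pixels.
#' @param pixelSize ground sampling distance in metres.
#' @param classSpectra 2 x 3 matrix of mean reflectance (rows target/other,
#'   columns green/red/nir).
#' @param classSpread per-class smooth-field standard deviation: a length-2
#'   numeric (same for all bands) or a 2 x 3 matrix.
#' @param textureAmplitude length-2 numeric, per-class standard deviation of
#'   pixel-scale noise; the target entry must be strictly larger.
#' @param patchCoverage fraction of the scene covered by target patches,
#'   in (0, 1).
#' @param patchScale Gaussian smoothing length (pixels) of the patch field;
#'   controls patch size.
#' @param fieldScale smoothing length (pixels) of within-class reflectance
#'   fields.
#' @param seed integer seed; all randomness derives from it through
#'   per-stage sub-streams.
#' @return a validated [SceneConfig-class].
#' @examples
#' cfg <- sceneConfig(width = 64, height = 64, seed = 1)
#' mask <- generatePatchMask(cfg)
#' scene <- renderScene(mask, cfg)
#' @export
sceneConfig <- function(width = 256L, height = 256L, pixelSize = 0.5,
                        classSpectra = rbind(
                          target = c(green = 0.10, red = 0.09, nir = 0.55),
                          other  = c(green = 0.09, red = 0.10, nir = 0.42)),
                        classSpread = c(target = 0.02, other = 0.02),
                        textureAmplitude = c(target = 0.08, other = 0.005),
                        patchCoverage = 0.3, patchScale = 10,
                        fieldScale = 8, seed = 1L) {
  if (length(width) != 1L || length(height) != 1L ||
      is.na(width) || is.na(height) || width < 1 || height < 1) {
    stop("scene dimensions must be positive integers")
  }
  if (!is.matrix(classSpread)) {
    classSpread <- matrix(rep(as.numeric(classSpread), 3L), nrow = 2L,
                          dimnames = list(c("target", "other"),
                                          c("green", "red", "nir")))
  }
  new("SceneConfig",
      width = as.integer(width), height = as.integer(height),
      pixelSize = as.numeric(pixelSize),
      classSpectra = classSpectra, classSpread = classSpread,
      textureAmplitude = as.numeric(textureAmplitude),
      patchCoverage = as.numeric(patchCoverage),
      patchScale = as.numeric(patchScale),
      fieldScale = as.numeric(fieldScale),
      seed = as.integer(seed))
}

#' Generate a labelled patch mask
#'
#' Thresholds a Gaussian-smoothed white-noise field at the quantile giving
#' the requested coverage, so that a single smoothing length controls both
#' patch size and spatial contiguity while the target-pixel fraction tracks
#' `patchCoverage` closely. Deterministic given the configuration seed.
#'
#' @param config a [SceneConfig-class].
#' @return a [LabelRaster-class] with codes 1 (target weed) and
#'   2 (other vegetation).
#' @export
generatePatchMask <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  field <- withSeed(deriveSeed(config@seed, 1L), {
    gaussianSmooth(matrix(rnorm(config@height * config@width),
                          config@height, config@width),
                   config@patchScale)
  })
  thr <- quantile(field, probs = 1 - config@patchCoverage, names = FALSE)
  labels <- matrix(2L, config@height, config@width)
  labels[field > thr] <- 1L
  new("LabelRaster", labels = labels)
}

#' Render a multispectral scene over a patch mask
#'
#' Per-pixel reflectance in each band is the class mean plus a smooth
#' per-class Gaussian field (standard deviation `classSpread`) plus
#' high-frequency zero-mean Gaussian noise scaled by the class's
#' `textureAmplitude`, clipped to \[0, 1\]. Band grids are stored on the
#' 32-bit TIFF sample grid (spacing `2^-32`) so they round-trip losslessly
#' through [writeScene()] / [readScene()].
#' Deterministic given the configuration seed; mask, smooth fields and
#' texture noise use independent sub-streams.
#'
#' @param mask a [LabelRaster-class] matching the configuration's
#'   dimensions.
#' @param config a [SceneConfig-class].
#' @return a [MultibandScene-class]; pixels labelled 0 in `mask` become
#'   nodata.
#' @export
renderScene <- function(mask, config) {
  stopifnot(is(mask, "LabelRaster"), is(config, "SceneConfig"))
  validObject(mask); validObject(config)
  h <- config@height; w <- config@width
  if (!identical(dim(mask@labels), c(h, w))) {
    stop("mask dimensions ", paste(dim(mask@labels), collapse = "x"),
         " do not match the configuration (", h, "x", w, ")")
  }
  present <- sort(unique(as.vector(mask@labels[mask@labels != 0L])))
  if (!all(present %in% c(1L, 2L)) ||
      any(present > nrow(config@classSpectra))) {
    stop("mask references a class with no configured spectra")
  }
  ## One smooth field and one pixel-scale noise field per class, shared by
  ## all bands and scaled per band/class: within-class reflectance varies
  ## mostly in common mode (canopy vigour, shading and roughness move the
  ## whole spectral signature together), which is also what lets a single
  ## band's texture carry the class contrast.
  fields <- lapply(c(1L, 2L), function(cls) {
    f <- withSeed(deriveSeed(config@seed, 10L + cls), {
      gaussianSmooth(matrix(rnorm(h * w), h, w), config@fieldScale)
    })
    list(smooth = f / sd(f),
         noise = withSeed(deriveSeed(config@seed, 30L + cls), {
           matrix(rnorm(h * w), h, w)
         }))
  })
  bands <- list(green = NULL, red = NULL, nir = NULL)
  for (b in seq_along(bands)) {
    band <- matrix(0, h, w)
    for (cls in c(1L, 2L)) {
      sel <- mask@labels == cls
      if (!any(sel)) next
      band[sel] <- config@classSpectra[cls, b] +
        fields[[cls]]$smooth[sel] * config@classSpread[cls, b] +
        fields[[cls]]$noise[sel] * config@textureAmplitude[cls]
    }
    band[band < 0] <- 0
    band[band > 1] <- 1
    bands[[b]] <- tiffQuantize(band)
  }
  nodata <- mask@labels == 0L
  for (b in seq_along(bands)) bands[[b]][nodata] <- NA_real_
  new("MultibandScene", green = bands$green, red = bands$red,
      nir = bands$nir, nodataMask = nodata, pixelSize = config@pixelSize)
}

#' Simulate a labelled scene in one call
#'
#' @inheritParams generatePatchMask
#' @return list with elements `scene` ([MultibandScene-class]) and
#'   `labels` ([LabelRaster-class]).
#' @export
simulateScene <- function(config) {
  mask <- generatePatchMask(config)
  list(scene = renderScene(mask, config), labels = mask)
}

#' @describeIn MultibandScene-class dimensions as (rows, cols).
#' @param x a `MultibandScene`.
#' @export
setMethod("dim", "MultibandScene", function(x) dim(x@green))

setMethod("show", "MultibandScene", function(object) {
  d <- dim(object@green)
  cat("MultibandScene:", d[1L], "x", d[2L], "pixels,",
      sum(object@nodataMask), "nodata |",
      "pixel size", object@pixelSize, "m\n")
  for (b in c("green", "red", "nir")) {
    v <- slot(object, b)[!object@nodataMask]
    cat(sprintf("  %-5s mean %.4f  sd %.4f\n", b, mean(v), sd(v)))
  }
})

setMethod("show", "LabelRaster", function(object) {
  d <- dim(object@labels)
  tab <- tabulate(object@labels + 1L, nbins = 3L)
  cat("LabelRaster:", d[1L], "x", d[2L], "pixels |",
      "target", tab[2L], "| other", tab[3L], "| nodata", tab[1L], "\n")
})
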