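#' Read and write multiband scenes as TIFF + JSON sidecar
#'
#' Scenes are stored as a 3-band 32-bit TIFF (band order green, red, NIR)
#' together with a JSON sidecar (`<path>.json`) carrying the pixel size and
#' a run-length encoding of the nodata mask. Band grids are held on the
#' 32-bit TIFF sample grid in memory, so the round trip
#' `readScene(writeScene(x))` reproduces every valid band value bit-exactly.
#' On disk, nodata pixels store 0; in memory they are `NA`.
#'
#' @param scene a [MultibandScene-class].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `writeScene` returns `path` invisibly; `readScene` returns a
#'   [MultibandScene-class].
#' @export
writeScene <- function(scene, path) {
  stopifnot(is(scene, "MultibandScene"))
  validObject(scene)
  d <- dim(scene@green)
  a <- array(0, dim = c(d, 3L))
  a[, , 1L] <- tiffEncode(scene@green)
  a[, , 2L] <- tiffEncode(scene@red)
  a[, , 3L] <- tiffEncode(scene@nir)
  a[is.na(a)] <- 0
  tiff::writeTIFF(a, path, bits.per.sample = 32L, compression = "none")
  rleMask <- rle(as.vector(scene@nodataMask))
  meta <- list(format = "weednov-scene", version = 1L,
               pixel_size = scene@pixelSize,
               nrow = d[1L], ncol = d[2L],
               nodata_rle = list(lengths = rleMask$lengths,
                                 values = rleMask$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeScene
#' @export
readScene <- function(path) {
  if (!file.exists(path)) stop("scene file not found: ", path)
  a <- tiff::readTIFF(path)
  if (length(dim(a)) != 3L || dim(a)[3L] != 3L) {
    nb <- if (length(dim(a)) == 3L) dim(a)[3L] else 1L
    stop("expected a 3-band scene but '", path, "' has ", nb, " band(s)")
  }
  sidecar <- paste0(path, ".json")
  pixelSize <- 0.5
  mask <- matrix(FALSE, dim(a)[1L], dim(a)[2L])
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size)) pixelSize <- meta$pixel_size
    if (!is.null(meta$nodata_rle)) {
      mv <- inverse.rle(structure(list(
        lengths = as.integer(meta$nodata_rle$lengths),
        values = as.logical(meta$nodata_rle$values)), class = "rle"))
      mask <- matrix(mv, dim(a)[1L], dim(a)[2L])
    }
  }
  bands <- list(a[, , 1L], a[, , 2L], a[, , 3L])
  bands <- lapply(bands, function(b) { b[mask] <- NA_real_; b })
  new("MultibandScene", green = bands[[1L]], red = bands[[2L]],
      nir = bands[[3L]], nodataMask = mask, pixelSize = pixelSize)
}

#' Read and write label rasters as single-band 8-bit TIFF
#'
#' Codes 0 (nodata), 1 (target weed), 2 (other vegetation) are stored in an
#' 8-bit single-band TIFF.
#'
#' @param labels a [LabelRaster-class].
#' @param path TIFF file path.
#' @return `writeLabels` returns `path` invisibly; `readLabels` a
#'   [LabelRaster-class].
#' @export
writeLabels <- function(labels, path) {
  stopifnot(is(labels, "LabelRaster"))
  validObject(labels)
  tiff::writeTIFF(labels@labels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) {
    if (dim(m)[3L] != 1L) {
      stop("expected a single-band label raster but '", path, "' has ",
           dim(m)[3L], " bands")
    }
    m <- m[, , 1L]
  }
  storage.mode(m) <- "integer"
  new("LabelRaster", labels = m)
}
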