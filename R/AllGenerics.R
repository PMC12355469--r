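#' @describeIn HSImage constructor.
#' @param cube numeric array (y, x, channel).
#' @param wavenumbers numeric axis in cm^-1, strictly increasing.
#' @param pixelSize micrometres per pixel.
#' @param modality "raman", "hsSRS" or "srs_frames".
#' @param metadata named list.
#' @export
HSImage <- function(cube, wavenumbers, pixelSize = 0.3,
                    modality = "raman", metadata = list()) {
  new("HSImage", cube = cube, wavenumbers = as.numeric(wavenumbers),
      pixelSize = pixelSize, modality = modality, metadata = metadata)
}

#' Spectral axis accessor
#' @param object an object carrying a wavenumber axis.
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "HSImage", function(object) object@wavenumbers)

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "ComponentSet", function(object) object@wavenumbers)

#' Cube data accessor
#' @param object an [HSImage-class].
#' @export
setGeneric("cubeData", function(object) standardGeneric("cubeData"))

#' @rdname cubeData
#' @export
setMethod("cubeData", "HSImage", function(object) object@cube)

#' Pixel size accessor (micrometres)
#' @param object an [HSImage-class].
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "HSImage", function(object) object@pixelSize)

#' Modality accessor
#' @param object an [HSImage-class].
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' @rdname modality
#' @export
setMethod("modality", "HSImage", function(object) object@modality)

#' @export
setMethod("dim", "HSImage", function(x) dim(x@cube))

setMethod("show", "HSImage", function(object) {
  d <- dim(object@cube)
  cat(sprintf("HSImage: %d x %d pixels, %d channels (%.0f-%.0f cm-1)\n",
              d[1], d[2], d[3], min(object@wavenumbers),
              max(object@wavenumbers)))
  cat(sprintf("  modality: %s, pixel size: %.3g um\n",
              object@modality, object@pixelSize))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Component spectra accessor
#' @param object a [ComponentSet-class].
#' @export
setGeneric("componentSpectra", function(object)
  standardGeneric("componentSpectra"))

#' @rdname componentSpectra
#' @export
setMethod("componentSpectra", "ComponentSet", function(object) object@S)

#' Concentration maps accessor
#'
#' @param object a [ComponentSet-class].
#' @return a (ny, nx, k) array of concentration images.
#' @export
setGeneric("concentrationMaps", function(object)
  standardGeneric("concentrationMaps"))

#' @rdname concentrationMaps
#' @export
setMethod("concentrationMaps", "ComponentSet", function(object) {
  array(object@concentration,
        dim = c(object@mapDim, ncol(object@concentration)))
})

#' Concentration matrix accessor (pixels x components)
#' @param object a [ComponentSet-class].
#' @export
setGeneric("concentrationMatrix", function(object)
  standardGeneric("concentrationMatrix"))

#' @rdname concentrationMatrix
#' @export
setMethod("concentrationMatrix", "ComponentSet",
          function(object) object@concentration)

#' Lack-of-fit accessor (percent)
#' @param object a [ComponentSet-class].
#' @export
setGeneric("lofPercent", function(object) standardGeneric("lofPercent"))

#' @rdname lofPercent
#' @export
setMethod("lofPercent", "ComponentSet", function(object) object@lofPercent)

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf(
    "ComponentSet: %d components, %d pixels, %d channels\n",
    nrow(object@S), nrow(object@concentration), ncol(object@S)))
  cat(sprintf("  LOF %.3f%% after %d iterations (converged: %s)\n",
              object@lofPercent, object@iterations, object@converged))
  if (length(object@signalFractions))
    cat("  signal fractions (%):",
        paste(sprintf("%.1f", object@signalFractions), collapse = " "), "\n")
})

#' VIP accessor
#' @param object a fitted [OPLSModel-class].
#' @export
setGeneric("vipScores", function(object) standardGeneric("vipScores"))

#' @rdname vipScores
#' @export
setMethod("vipScores", "OPLSModel", function(object) object@vip)

setMethod("show", "OPLSModel", function(object) {
  cat(sprintf(
    "OPLS-DA model: 1 predictive + %d orthogonal components, %d channels\n",
    object@nOrtho, length(object@weightsPred)))
  cat(sprintf("  R2X(cum) = %.1f%%; %d channels with VIP > 1\n",
              object@r2xTotal, sum(object@vip > 1)))
  cat(sprintf("  classes: %s (+1) vs %s (-1)\n",
              object@classLevels[1], object@classLevels[2]))
})

setMethod("show", "PhasorMap", function(object) {
  cat(sprintf("PhasorMap: %d x %d pixels, harmonic %d, %d valid pixels\n",
              nrow(object@G), ncol(object@G), object@harmonic,
              sum(object@validMask)))
})

setMethod("show", "RegionSegmentation", function(object) {
  tab <- table(factor(object@labels,
                      levels = 0:length(object@regionNames),
                      labels = c("background", object@regionNames)))
  cat("RegionSegmentation:\n")
  print(tab)
})
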