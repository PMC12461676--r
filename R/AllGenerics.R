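#' @include AllClasses.R
NULL

#' Number of spatial pixels and channels of a cube
#'
#' @param x an \code{MSIDataCube}.
#' @return integer vector (X, Y, H).
#' @export
setMethod("dim", "MSIDataCube", function(x) dim(x@intensities))

#' Access the intensity array of a cube
#' @param object an \code{MSIDataCube}.
#' @return the X x Y x H numeric array.
#' @export
setGeneric("intensityArray", function(object) standardGeneric("intensityArray"))

#' @rdname intensityArray
#' @export
setMethod("intensityArray", "MSIDataCube", function(object) object@intensities)

#' Access the m/z axis of a cube
#' @param object an \code{MSIDataCube}.
#' @return numeric vector of m/z values (Th), strictly increasing.
#' @export
setGeneric("mzAxis", function(object) standardGeneric("mzAxis"))

#' @rdname mzAxis
#' @export
setMethod("mzAxis", "MSIDataCube", function(object) object@mzAxis)

#' Access the pixel mask of a cube
#' @param object an \code{MSIDataCube}.
#' @return logical X x Y matrix (TRUE = acquired tissue pixel).
#' @export
setGeneric("pixelMask", function(object) standardGeneric("pixelMask"))

#' @rdname pixelMask
#' @export
setMethod("pixelMask", "MSIDataCube", function(object) object@pixelMask)

#' Access cube metadata
#' @param object an \code{MSIDataCube}.
#' @return list of provenance key/values.
#' @export
setGeneric("cubeMeta", function(object) standardGeneric("cubeMeta"))

#' @rdname cubeMeta
#' @export
setMethod("cubeMeta", "MSIDataCube", function(object) object@meta)

#' Access the pixel matrix of an ion image
#' @param object an \code{IonImage}.
#' @return numeric X x Y matrix.
#' @export
setGeneric("ionPixels", function(object) standardGeneric("ionPixels"))

#' @rdname ionPixels
#' @export
setMethod("ionPixels", "IonImage", function(object) object@pixels)

#' Access the m/z value of an ion image
#' @param object an \code{IonImage}.
#' @return numeric m/z (Th).
#' @export
setGeneric("ionMz", function(object) standardGeneric("ionMz"))

#' @rdname ionMz
#' @export
setMethod("ionMz", "IonImage", function(object) object@mz)

#' @export
setMethod("show", "MSIDataCube", function(object) {
  d <- dim(object@intensities)
  cat(sprintf(
    "MSIDataCube: %d x %d pixels, %d m/z channels (%.4f - %.4f Th)\n",
    d[1], d[2], d[3], min(object@mzAxis), max(object@mzAxis)
  ))
  cat(sprintf(
    "  acquired pixels: %d / %d; intensity range [%.4g, %.4g]\n",
    sum(object@pixelMask), d[1] * d[2],
    min(object@intensities), max(object@intensities)
  ))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "IonImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "IonImage: m/z %.4f (channel %s), %d x %d pixels, max %.4g\n",
    object@mz,
    ifelse(is.na(object@channelIndex), "NA", as.character(object@channelIndex)),
    d[1], d[2], max(object@pixels)
  ))
  invisible(NULL)
})

#' @export
setMethod("show", "DenoiserModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(
    "DenoiserModel: base %d channels, depth %d, %s parameters%s\n",
    object@arch$baseChannels, object@arch$depth, format(np, big.mark = ","),
    if (length(object@history)) sprintf(" (trained %d epochs)", length(object@history)) else " (untrained)"
  ))
  invisible(NULL)
})

#' @export
setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (mean +/- sd across channels):\n")
  a <- object@aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf(
      "  %-10s PSNR %6.2f +/- %5.2f dB   SSIM %5.3f +/- %5.3f\n",
      a$method[i], a$mean_psnr[i], a$sd_psnr[i], a$mean_ssim[i], a$sd_ssim[i]
    ))
  invisible(NULL)
})
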