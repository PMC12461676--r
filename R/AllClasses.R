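#' @import methods
NULL

#' MSIDataCube: an X x Y x H mass spectrometry imaging datacube
#'
#' The central container of the package: a three-dimensional array of
#' nonnegative ion intensities with two spatial axes (X = horizontal pixel
#' index, stored as the first array dimension; Y = vertical pixel index) and
#' one m/z axis of length H (one ion image per m/z bin). Unacquired or
#' off-tissue pixels are recorded in \code{pixelMask} and carry intensity 0;
#' zeros are the encoding for missing values throughout the package.
#'
#' @slot intensities numeric 3-D array, dim (X, Y, H), all values >= 0.
#' @slot mzAxis numeric vector of length H, strictly increasing m/z values (Th).
#' @slot pixelMask logical X x Y matrix; TRUE marks acquired tissue pixels.
#' @slot meta list of free-form provenance (source file, pixel size, polarity,
#'   per-channel normalization scales written by \code{\link{preprocessCube}}).
#'
#' @seealso \code{\link{MSIDataCube}} (constructor), \code{\link{getIonImage}},
#'   \code{\link{readMSICube}}, \code{\link{preprocessCube}}
#' @export
setClass("MSIDataCube",
  slots = c(
    intensities = "array",
    mzAxis = "numeric",
    pixelMask = "matrix",
    meta = "list"
  )
)

setValidity("MSIDataCube", function(object) {
  d <- dim(object@intensities)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "'intensities' must be a 3-D array (X, Y, H)")
  else {
    if (any(d < 1L))
      msg <- c(msg, "all cube dimensions must be >= 1")
    if (d[3L] != length(object@mzAxis))
      msg <- c(msg, "length of 'mzAxis' must equal dim(intensities)[3]")
    if (!identical(dim(object@pixelMask), d[1:2]))
      msg <- c(msg, "'pixelMask' must be an X x Y logical matrix")
  }
  if (length(object@mzAxis) > 1L && any(diff(object@mzAxis) <= 0))
    msg <- c(msg, "'mzAxis' must be strictly increasing")
  if (anyNA(object@intensities) || any(object@intensities < 0))
    msg <- c(msg, "intensities must be finite and >= 0 (missing values are encoded as 0)")
  if (!is.logical(object@pixelMask) || anyNA(object@pixelMask))
    msg <- c(msg, "'pixelMask' must be logical with no NA")
  if (length(msg)) msg else TRUE
})

#' IonImage: a single ion image (one m/z channel of a cube)
#'
#' @slot pixels numeric X x Y matrix of nonnegative intensities.
#' @slot mz m/z value of the channel (Th).
#' @slot channelIndex integer index of the channel in its parent cube
#'   (1-based; \code{NA} for free-standing images).
#'
#' @seealso \code{\link{getIonImage}}
#' @export
setClass("IonImage",
  slots = c(
    pixels = "matrix",
    mz = "numeric",
    channelIndex = "integer"
  )
)

setValidity("IonImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels))
    msg <- c(msg, "'pixels' must be a numeric matrix")
  if (anyNA(object@pixels) || any(object@pixels < 0))
    msg <- c(msg, "pixel intensities must be finite and >= 0")
  if (length(object@mz) != 1L)
    msg <- c(msg, "'mz' must be a single value")
  if (length(msg)) msg else TRUE
})

#' DenoiserModel: convolutional encoder-decoder denoiser f(. | theta)
#'
#' Holds the learnable weights theta and the architecture description of the
#' U-Net-style denoising network: per encoder level two 3x3 convolutions with
#' ReLU followed by 2x2 max pooling, channels doubling from
#' \code{baseChannels}; a bottleneck at \code{baseChannels * 2^depth}; a
#' mirrored decoder with bilinear 2x upsampling and copy-and-concatenate skip
#' connections; and a final linear 1x1 convolution to one channel.
#'
#' @slot params list of layer parameter matrices/vectors (the weights theta).
#' @slot arch list describing the architecture (baseChannels, depth, kernel).
#' @slot trainConfig list; the configuration the model was (last) trained with.
#' @slot history numeric vector of per-epoch training loss (empty if untrained).
#' @slot valHistory numeric vector of per-epoch validation loss.
#'
#' @seealso \code{\link{buildDenoiser}}, \code{\link{trainDenoiser}},
#'   \code{\link{denoiseCube}}
#' @export
setClass("DenoiserModel",
  slots = c(
    params = "list",
    arch = "list",
    trainConfig = "list",
    history = "numeric",
    valHistory = "numeric"
  )
)

#' EvalReport: per-channel and aggregate PSNR/SSIM of denoising methods
#'
#' @slot perChannel data.frame with columns channel, mz, method, psnr, ssim.
#' @slot aggregate data.frame with columns method, mean_psnr, sd_psnr,
#'   mean_ssim, sd_ssim.
#'
#' @seealso \code{\link{evaluateMethods}}
#' @export
setClass("EvalReport",
  slots = c(
    perChannel = "data.frame",
    aggregate = "data.frame"
  )
)
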