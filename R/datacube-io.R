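#' Construct an MSIDataCube
#'
#' @param intensities numeric 3-D array, dim (X, Y, H); X indexes the
#'   horizontal pixel coordinate, Y the vertical one, H the m/z bins.
#' @param mz numeric vector of length H, strictly increasing m/z values (Th).
#' @param mask logical X x Y matrix of acquired pixels; default all TRUE.
#'   Mask-FALSE pixels are forced to intensity 0.
#' @param meta list of provenance key/values.
#' @return a valid \code{\linkS4class{MSIDataCube}}.
#' @examples
#' cube <- MSIDataCube(array(runif(2 * 2 * 3), c(2, 2, 3)), mz = c(100, 200, 300))
#' dim(cube)
#' @export
MSIDataCube <- function(intensities, mz, mask = NULL, meta = list()) {
  intensities <- as.array(intensities)
  storage.mode(intensities) <- "double"
  if (length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3-D array (X, Y, H)")
  if (is.null(mask)) mask <- matrix(TRUE, dim(intensities)[1], dim(intensities)[2])
  if (any(!mask)) {
    # unacquired pixels carry zero intensity by convention
    intensities[which(array(!mask, dim(intensities)))] <- 0
  }
  new("MSIDataCube",
    intensities = intensities, mzAxis = as.numeric(mz),
    pixelMask = mask, meta = meta
  )
}

#' Extract one ion image from a cube
#'
#' The returned image is an independent copy: mutating it never affects the
#' parent cube.
#'
#' @param cube an \code{MSIDataCube}.
#' @param channel 1-based channel index (1 <= channel <= H).
#' @return an \code{\linkS4class{IonImage}} carrying the channel's m/z.
#' @export
getIonImage <- function(cube, channel) {
  stopifnot(is(cube, "MSIDataCube"))
  H <- dim(cube@intensities)[3]
  channel <- as.integer(channel)
  if (length(channel) != 1L || is.na(channel) || channel < 1L || channel > H)
    stop(sprintf("channel index out of range: must be in [1, %d]", H))
  new("IonImage",
    pixels = cube@intensities[, , channel, drop = TRUE],
    mz = cube@mzAxis[channel], channelIndex = channel
  )
}

#' Replace one channel of a cube (returns a modified copy)
#'
#' @param cube an \code{MSIDataCube}.
#' @param channel 1-based channel index.
#' @param pixels numeric X x Y matrix.
#' @return the modified cube.
#' @export
setIonImage <- function(cube, channel, pixels) {
  stopifnot(is(cube, "MSIDataCube"))
  cube@intensities[, , channel] <- asPixels(pixels)
  validObject(cube)
  cube
}

#' Read an MSI datacube from disk
#'
#' Supports two formats: the package's native RDS matrix container (a named
#' list with elements \code{intensities}, \code{mz}, \code{mask}, \code{meta})
#' and imzML (continuous or processed mode, with the binary \code{.ibd} file
#' expected next to the XML). Processed-mode spectra are binned onto a common
#' m/z axis by greedy merging of peaks within \code{ppm} of a running bin
#' center (the center is the mean m/z of the peaks merged so far).
#'
#' @param path file path (\code{.rds} or \code{.imzML}).
#' @param format \code{"auto"} (by extension), \code{"rds"} or \code{"imzml"}.
#' @param ppm bin tolerance in parts per million for processed-mode imzML.
#' @return an \code{\linkS4class{MSIDataCube}}.
#' @seealso \code{\link{writeMSICube}}
#' @export
readMSICube <- function(path, format = c("auto", "rds", "imzml"), ppm = 10) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read MSI cube: no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml" else "rds"
  }
  if (format == "rds") {
    obj <- readRDS(path)
    if (!is.list(obj) || !all(c("intensities", "mz") %in% names(obj)))
      stop("not an MSI matrix container (expected elements 'intensities', 'mz'): ", path)
    meta <- obj$meta
    if (is.character(meta)) meta <- jsonlite::fromJSON(meta, simplifyVector = TRUE)
    if (is.null(meta)) meta <- list()
    meta$source_file <- path
    MSIDataCube(obj$intensities, obj$mz, mask = obj$mask, meta = meta)
  } else {
    readImzML(path, ppm = ppm)
  }
}

#' Write an MSI datacube to disk
#'
#' @param cube an \code{MSIDataCube}.
#' @param path output path; the imzML writer also creates the sibling
#'   \code{.ibd} binary file.
#' @param format \code{"auto"}, \code{"rds"} or \code{"imzml"}.
#' @param mode imzML spectrum storage mode; \code{"continuous"} shares one m/z
#'   array across pixels, \code{"processed"} stores only nonzero peaks per
#'   pixel.
#' @return invisibly, \code{path}.
#' @export
writeMSICube <- function(cube, path, format = c("auto", "rds", "imzml"),
                         mode = c("continuous", "processed")) {
  stopifnot(is(cube, "MSIDataCube"))
  validObject(cube)
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (format == "auto") {
    format <- if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml" else "rds"
  }
  if (format == "rds") {
    meta <- cube@meta
    meta$source_file <- NULL
    obj <- list(
      intensities = cube@intensities, mz = cube@mzAxis,
      mask = cube@pixelMask,
      meta = jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
    )
    ok <- tryCatch({ saveRDS(obj, path); TRUE },
      error = function(e) stop("cannot write MSI cube to ", path, ": ", conditionMessage(e))
    )
  } else {
    writeImzML(cube, path, mode = mode)
  }
  invisible(path)
}
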