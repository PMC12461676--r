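#' Corruption configuration for quantitative evaluation
#'
#' The evaluation protocol degrades clean reference images with two
#' mechanisms typical of mass analyzers: Poisson resampling of each pixel
#' (draw with the pixel value as the mean) and random missing values (an
#' exact fraction of mask-true pixels set to zero).
#'
#' @param missing_frac fraction of mask-true pixels zeroed per channel
#'   (default 0.20).
#' @param poisson_scale counts-per-unit-intensity S: each pixel is replaced by
#'   Poisson(S * value) / S. The default S = 1 takes the pixel value itself as
#'   the Poisson mean, which on [0, 1]-normalized images is very destructive
#'   (draws are small integers); larger S emulates pre-normalization count
#'   levels.
#' @param seed RNG seed; per-channel substreams are derived from it.
#' @return a validated list of class \code{CorruptionConfig}.
#' @export
corruptionConfig <- function(missing_frac = 0.20, poisson_scale = 1.0, seed = 1L) {
  stopifnot(
    missing_frac >= 0, missing_frac < 1,
    poisson_scale > 0
  )
  structure(
    list(
      missing_frac = missing_frac, poisson_scale = poisson_scale,
      seed = as.integer(seed)
    ),
    class = c("CorruptionConfig", "list")
  )
}

#' Poisson-resample an ion image
#'
#' Replaces every pixel value v by a draw from Poisson(S * v) / S. Zero pixels
#' stay exactly zero (Poisson(0) is degenerate at 0), and the operator is
#' unbiased: E[output] = input.
#'
#' @param image an \code{IonImage} or numeric matrix with values >= 0.
#' @param scale the counts-per-unit-intensity factor S (default 1).
#' @param seed RNG seed for reproducibility (optional).
#' @return object of the same type as \code{image}.
#' @export
poissonCorrupt <- function(image, scale = 1.0, seed = NULL) {
  px <- asPixels(image)
  if (anyNA(px) || any(px < 0)) stop("poissonCorrupt requires nonnegative intensities")
  stopifnot(scale > 0)
  out <- withSeed(seed, stats::rpois(length(px), lambda = scale * px) / scale)
  likeInput(image, matrix(out, nrow(px), ncol(px)))
}

#' Zero an exact fraction of pixels at random
#'
#' Samples exactly \code{floor(frac * n)} distinct mask-true pixels (n = their
#' count) without replacement and sets them to zero; all other pixels are
#' untouched.
#'
#' @param image an \code{IonImage} or numeric matrix.
#' @param frac fraction of mask-true pixels to zero, in [0, 1) (default 0.20).
#' @param seed RNG seed (optional).
#' @param mask optional logical matrix; defaults to all pixels eligible.
#' @return object of the same type as \code{image}.
#' @export
missingCorrupt <- function(image, frac = 0.20, seed = NULL, mask = NULL) {
  stopifnot(frac >= 0, frac < 1)
  px <- asPixels(image)
  mask <- resolveMask(px, mask)
  eligible <- which(mask)
  n_zero <- floor(frac * length(eligible))
  if (n_zero > 0) {
    hit <- withSeed(seed, sample(eligible, n_zero))
    px[hit] <- 0
  }
  likeInput(image, px)
}

#' Corrupt a whole datacube for evaluation
#'
#' Per channel: Poisson resampling followed by exact-fraction missing-value
#' injection, each channel on an independent RNG substream derived from the
#' seed. The input cube is not modified.
#'
#' @param cube an \code{MSIDataCube}.
#' @param config a \code{\link{corruptionConfig}}.
#' @return the corrupted cube.
#' @export
corruptCube <- function(cube, config = corruptionConfig()) {
  stopifnot(is(cube, "MSIDataCube"))
  H <- dim(cube@intensities)[3]
  seeds <- deriveSeeds(config$seed, 2L * H)
  for (k in seq_len(H)) {
    ch <- poissonCorrupt(cube@intensities[, , k],
      scale = config$poisson_scale, seed = seeds[2L * k - 1L])
    ch <- missingCorrupt(ch, frac = config$missing_frac,
      seed = seeds[2L * k], mask = cube@pixelMask)
    cube@intensities[, , k] <- ch
  }
  cube@meta$corruption <- list(
    missing_frac = config$missing_frac,
    poisson_scale = config$poisson_scale, seed = config$seed
  )
  cube
}
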