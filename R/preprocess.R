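#' Preprocessing configuration
#'
#' Settings for \code{\link{preprocessCube}}. The pipeline applies, in order:
#' per-pixel TIC normalization, per-ion hotspot truncation, per-ion max
#' normalization to [0, 1]. A hotspot is any pixel whose intensity exceeds
#' \code{hotspot_quantile_of_max} times the channel maximum (strict
#' inequality: ties at the threshold are kept).
#'
#' @param hotspot_quantile_of_max fraction of the channel maximum above which
#'   values are truncated (default 0.99).
#' @param do_tic apply TIC normalization (default TRUE).
#' @param do_hotspot apply hotspot truncation (default TRUE).
#' @param do_max_norm apply per-ion max normalization (default TRUE).
#' @param occupancy_min optional: drop channels whose fraction of nonzero
#'   mask-true pixels is below this value (applied before the other steps);
#'   \code{NULL} (default) keeps all channels.
#' @return a validated list of class \code{PreprocessConfig}.
#' @export
preprocessConfig <- function(hotspot_quantile_of_max = 0.99, do_tic = TRUE,
                             do_hotspot = TRUE, do_max_norm = TRUE,
                             occupancy_min = NULL) {
  stopifnot(
    hotspot_quantile_of_max > 0, hotspot_quantile_of_max <= 1,
    is.logical(do_tic), is.logical(do_hotspot), is.logical(do_max_norm),
    is.null(occupancy_min) || (occupancy_min >= 0 && occupancy_min < 1)
  )
  structure(
    list(
      hotspot_quantile_of_max = hotspot_quantile_of_max,
      do_tic = do_tic, do_hotspot = do_hotspot, do_max_norm = do_max_norm,
      occupancy_min = occupancy_min
    ),
    class = c("PreprocessConfig", "list")
  )
}

#' Total ion current (TIC) normalization
#'
#' Divides each mask-true pixel's spectrum by its summed intensity, so every
#' pixel with nonzero TIC has a spectrum summing to 1. All-zero pixels are
#' left untouched.
#'
#' @param cube an \code{MSIDataCube}.
#' @return the TIC-normalized cube.
#' @export
ticNormalize <- function(cube) {
  stopifnot(is(cube, "MSIDataCube"))
  d <- dim(cube@intensities)
  flat <- matrix(cube@intensities, nrow = d[1] * d[2], ncol = d[3])
  tic <- rowSums(flat)
  # mask-false pixels are all-zero by convention, so no special-casing needed
  flat <- flat * ifelse(tic > 0, 1 / tic, 1)
  cube@intensities <- array(flat, d)
  cube@meta$tic <- matrix(tic, d[1], d[2])
  cube
}

#' Hotspot truncation
#'
#' Clips anomalously intense pixels: with \code{m} the maximum over mask-true
#' pixels, every value strictly exceeding \code{q * m} is set to \code{q * m}.
#' Values at or below the threshold are unchanged; an all-zero image is
#' returned unchanged.
#'
#' @param image an \code{IonImage} or numeric matrix.
#' @param q fraction of the maximum defining the hotspot threshold, in (0, 1].
#' @param mask optional logical matrix restricting the maximum computation;
#'   default: all pixels.
#' @return object of the same type as \code{image}.
#' @examples
#' truncateHotspots(matrix(c(0, 0.5, 1), 1), q = 0.99)  # -> 0, 0.5, 0.99
#' @export
truncateHotspots <- function(image, q = 0.99, mask = NULL) {
  stopifnot(q > 0, q <= 1)
  px <- asPixels(image)
  mask <- resolveMask(px, mask)
  m <- if (any(mask)) max(px[mask]) else 0
  if (m > 0) {
    thr <- q * m
    px[px > thr] <- thr
  }
  likeInput(image, px)
}

#' Per-ion max normalization to [0, 1]
#'
#' Divides the image by its maximum over mask-true pixels; all-zero images are
#' returned unchanged.
#'
#' @inheritParams truncateHotspots
#' @return object of the same type as \code{image}, with maximum 1 (or all 0).
#' @export
maxNormalize <- function(image, mask = NULL) {
  px <- asPixels(image)
  mask <- resolveMask(px, mask)
  m <- if (any(mask)) max(px[mask]) else 0
  if (m > 0) px <- px / m
  likeInput(image, px)
}

#' Preprocess a datacube
#'
#' Applies, in order: optional occupancy-based channel dropping, per-pixel TIC
#' normalization, per-ion hotspot truncation, and per-ion max normalization.
#' The per-channel scale factors divided out by max normalization are recorded
#' in \code{cubeMeta(cube)$channel_scale} so that downstream consumers (pair
#' mining) can recover pre-normalization mean intensities.
#'
#' @param cube an \code{MSIDataCube}.
#' @param config a \code{\link{preprocessConfig}}.
#' @return the preprocessed cube; every channel's maximum is 0 or 1 when
#'   \code{do_max_norm} is on.
#' @export
preprocessCube <- function(cube, config = preprocessConfig()) {
  stopifnot(is(cube, "MSIDataCube"))
  if (!is.null(config$occupancy_min)) {
    mask <- cube@pixelMask
    n_on <- sum(mask)
    occ <- apply(cube@intensities, 3, function(ch) sum(ch[mask] > 0) / max(n_on, 1L))
    keep <- occ >= config$occupancy_min
    if (!all(keep)) {
      cube@intensities <- cube@intensities[, , keep, drop = FALSE]
      cube@mzAxis <- cube@mzAxis[keep]
      cube@meta$dropped_channels <- which(!keep)
    }
  }
  if (config$do_tic) cube <- ticNormalize(cube)
  H <- dim(cube@intensities)[3]
  scales <- rep(1, H)
  for (k in seq_len(H)) {
    ch <- cube@intensities[, , k]
    if (config$do_hotspot)
      ch <- truncateHotspots(ch, config$hotspot_quantile_of_max, mask = cube@pixelMask)
    if (config$do_max_norm) {
      m <- if (any(cube@pixelMask)) max(ch[cube@pixelMask]) else 0
      if (m > 0) {
        ch <- ch / m
        scales[k] <- m
      }
    }
    cube@intensities[, , k] <- ch
  }
  if (config$do_max_norm) cube@meta$channel_scale <- scales
  cube@meta$preprocessed <- TRUE
  cube
}
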