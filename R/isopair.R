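#' Pair-mining configuration
#'
#' Settings for \code{\link{findIsotopePairs}}. A candidate pair is a channel
#' pair (mono, iso) whose m/z gap matches the +1 isotopologue spacing (one
#' 13C substitution) within a ppm tolerance; acceptance additionally requires
#' sufficient spatial correlation, an isotopic/monoisotopic abundance ratio
#' at most \code{max_ratio}, and minimum channel occupancy.
#'
#' @param isotope_spacing expected m/z gap in Th (default 1.003355, the
#'   13C-12C mass difference).
#' @param mz_tol_ppm tolerance on the gap, in ppm of the monoisotopic m/z
#'   (default 10).
#' @param min_corr minimum Pearson correlation over jointly nonzero mask-true
#'   pixels (default 0.6).
#' @param max_ratio maximum mean(iso)/mean(mono) intensity ratio, computed on
#'   pre-normalization intensities (default 1: the isotopologue cannot be
#'   more abundant than its monoisotopic peak).
#' @param min_occupancy minimum fraction of nonzero mask-true pixels per
#'   channel (default 0.05).
#' @param min_joint_pixels minimum number of jointly nonzero pixels for the
#'   correlation to be meaningful (default 10; pairs below are rejected).
#' @return a validated list of class \code{PairConfig}.
#' @export
pairConfig <- function(isotope_spacing = 1.003355, mz_tol_ppm = 10,
                       min_corr = 0.6, max_ratio = 1.0, min_occupancy = 0.05,
                       min_joint_pixels = 10L) {
  stopifnot(
    isotope_spacing > 0, mz_tol_ppm > 0,
    min_corr > 0, min_corr < 1, max_ratio > 0,
    min_occupancy >= 0, min_occupancy < 1, min_joint_pixels >= 3L
  )
  structure(
    list(
      isotope_spacing = isotope_spacing, mz_tol_ppm = mz_tol_ppm,
      min_corr = min_corr, max_ratio = max_ratio,
      min_occupancy = min_occupancy,
      min_joint_pixels = as.integer(min_joint_pixels)
    ),
    class = c("PairConfig", "list")
  )
}

#' Mine monoisotopic/isotopic ion-image pairs from a preprocessed cube
#'
#' Scans the m/z axis for channel pairs separated by the isotope spacing
#' (within \code{mz_tol_ppm} of the monoisotopic m/z), computes the Pearson
#' correlation of the two ion images over jointly nonzero mask-true pixels,
#' and accepts pairs passing the correlation, abundance-ratio and occupancy
#' filters. When one monoisotopic channel matches several isotopic
#' candidates, the highest correlation wins (ties: smallest deviation of the
#' gap from the isotope spacing). Accepted pairs are chain-broken: a channel
#' used as an isotopic partner is never accepted as another pair's
#' monoisotopic channel, and vice versa. Output rows are ordered by ascending
#' monoisotopic m/z.
#'
#' Abundance ratios are computed on pre-normalization intensities when the
#' cube carries the \code{channel_scale} factors recorded by
#' \code{\link{preprocessCube}}; otherwise on the stored intensities.
#'
#' @param cube a preprocessed \code{MSIDataCube} (channels max-normalized).
#' @param config a \code{\link{pairConfig}}.
#' @return data.frame with columns \code{mono_channel}, \code{iso_channel},
#'   \code{mono_mz}, \code{iso_mz}, \code{delta_mz}, \code{corr},
#'   \code{ratio}; zero rows when no pair passes (always for H < 2).
#' @export
findIsotopePairs <- function(cube, config = pairConfig()) {
  stopifnot(is(cube, "MSIDataCube"))
  cfg <- config
  empty <- data.frame(
    mono_channel = integer(), iso_channel = integer(),
    mono_mz = numeric(), iso_mz = numeric(), delta_mz = numeric(),
    corr = numeric(), ratio = numeric()
  )
  H <- dim(cube@intensities)[3]
  if (H < 2L) return(empty)

  mz <- cube@mzAxis
  mask <- cube@pixelMask
  n_on <- max(sum(mask), 1L)
  flat <- matrix(cube@intensities, ncol = H)[as.vector(mask), , drop = FALSE]
  occ <- colSums(flat > 0) / n_on
  scale <- cube@meta$channel_scale
  if (is.null(scale) || length(scale) != H) scale <- rep(1, H)
  pre_mean <- colMeans(flat) * scale

  cand <- list()
  for (i in seq_len(H - 1L)) {
    if (occ[i] < cfg$min_occupancy) next
    tol <- cfg$mz_tol_ppm * 1e-6 * mz[i]
    js <- which(mz > mz[i] + cfg$isotope_spacing - tol &
                mz < mz[i] + cfg$isotope_spacing + tol)
    for (j in js) {
      if (occ[j] < cfg$min_occupancy) next
      joint <- flat[, i] > 0 & flat[, j] > 0
      if (sum(joint) < cfg$min_joint_pixels) next
      r <- suppressWarnings(stats::cor(flat[joint, i], flat[joint, j]))
      if (is.na(r) || r < cfg$min_corr) next
      ratio <- pre_mean[j] / pre_mean[i]
      if (!is.finite(ratio) || ratio <= 0 || ratio > cfg$max_ratio) next
      cand[[length(cand) + 1L]] <- data.frame(
        mono_channel = i, iso_channel = j,
        mono_mz = mz[i], iso_mz = mz[j], delta_mz = mz[j] - mz[i],
        corr = r, ratio = ratio
      )
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)

  # best candidate per monoisotopic channel: highest correlation, ties broken
  # by smallest |delta_mz - spacing|
  cand <- cand[order(cand$mono_channel, -cand$corr,
    abs(cand$delta_mz - cfg$isotope_spacing)), ]
  cand <- cand[!duplicated(cand$mono_channel), ]

  # chain-breaking, ascending monoisotopic m/z
  cand <- cand[order(cand$mono_mz), ]
  used_iso <- integer(); used_mono <- integer()
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    mc <- cand$mono_channel[k]; ic <- cand$iso_channel[k]
    if (mc %in% used_iso || ic %in% used_mono || ic %in% used_iso) next
    keep[k] <- TRUE
    used_mono <- c(used_mono, mc)
    used_iso <- c(used_iso, ic)
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

#' Build the (input, target) training set from mined pairs
#'
#' Element i is a list with \code{input}: the isotopic ion image (the noisier
#' channel) and \code{target}: the monoisotopic ion image (the pseudo ground
#' truth), both max-normalized. The list length is the number of pairs N used
#' by the reconstruction loss.
#'
#' @param cube the preprocessed \code{MSIDataCube} the pairs refer to.
#' @param pairs data.frame from \code{\link{findIsotopePairs}}.
#' @return list of length \code{nrow(pairs)} of lists (input, target,
#'   mono_channel, iso_channel).
#' @export
buildTrainingSet <- function(cube, pairs) {
  stopifnot(is(cube, "MSIDataCube"), is.data.frame(pairs))
  H <- dim(cube@intensities)[3]
  if (nrow(pairs) == 0L) return(list())
  if (any(pairs$mono_channel < 1 | pairs$mono_channel > H |
          pairs$iso_channel < 1 | pairs$iso_channel > H))
    stop("pair table references channels outside the cube (1..", H, ")")
  lapply(seq_len(nrow(pairs)), function(k) {
    list(
      input = maxNormalize(cube@intensities[, , pairs$iso_channel[k]],
        mask = cube@pixelMask),
      target = maxNormalize(cube@intensities[, , pairs$mono_channel[k]],
        mask = cube@pixelMask),
      mono_channel = pairs$mono_channel[k],
      iso_channel = pairs$iso_channel[k]
    )
  })
}
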