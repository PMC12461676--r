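C13_SPACING <- 1.003355  # Th, mass difference between 13C and 12C

#' Phantom generator configuration
#'
#' Defines the synthetic study conditions: region-structured ion images
#' (organ-like blobs), planted monoisotopic/isotopic pairs in which the
#' isotopic channel is an abundance-scaled copy of its monoisotopic partner
#' with extra missing values and outliers, plus unpaired singleton ions and
#' pure-noise channels.
#'
#' @param shape integer (X, Y) pixel counts, each >= 8 (default 48 x 48).
#' @param n_regions number of organ-like region masks (default 5).
#' @param n_pairs number of planted isotope pairs (default 20).
#' @param n_unpaired number of singleton ion channels (default 10).
#' @param n_noise_channels number of pure-noise channels (default 5).
#' @param iso_abundance isotopic/monoisotopic abundance ratio in (0, 1)
#'   (default 0.3, a typical +1 isotopologue ratio for lipid-sized molecules).
#' @param iso_extra_missing extra missing-value fraction of isotopic channels
#'   beyond \code{base_missing} (default 0.15).
#' @param iso_outlier_frac fraction of isotopic-channel pixels replaced by
#'   high outliers (default 0.02).
#' @param base_missing missing-value fraction of monoisotopic channels
#'   (default 0.05).
#' @param noise_sigma sdlog of the multiplicative lognormal pixel noise
#'   (default 0.2).
#' @param seed RNG seed; the whole phantom is a deterministic function of it.
#' @return a validated list of class \code{PhantomConfig}.
#' @export
phantomConfig <- function(shape = c(48L, 48L), n_regions = 5L, n_pairs = 20L,
                          n_unpaired = 10L, n_noise_channels = 5L,
                          iso_abundance = 0.3, iso_extra_missing = 0.15,
                          iso_outlier_frac = 0.02, base_missing = 0.05,
                          noise_sigma = 0.2, seed = 1L) {
  stopifnot(
    length(shape) == 2L, all(shape >= 8L),
    n_regions >= 1L, n_pairs >= 0L, n_unpaired >= 0L, n_noise_channels >= 0L,
    iso_abundance > 0, iso_abundance < 1,
    iso_extra_missing >= 0, iso_extra_missing < 1,
    iso_outlier_frac >= 0, iso_outlier_frac < 1,
    base_missing >= 0, base_missing < 1, noise_sigma >= 0
  )
  structure(
    list(
      shape = as.integer(shape), n_regions = as.integer(n_regions),
      n_pairs = as.integer(n_pairs), n_unpaired = as.integer(n_unpaired),
      n_noise_channels = as.integer(n_noise_channels),
      iso_abundance = iso_abundance, iso_extra_missing = iso_extra_missing,
      iso_outlier_frac = iso_outlier_frac, base_missing = base_missing,
      noise_sigma = noise_sigma, seed = as.integer(seed)
    ),
    class = c("PhantomConfig", "list")
  )
}

# A smooth random field in [0, 1]: blurred white noise, min-max rescaled.
smoothField <- function(shape, sigma) {
  f <- gaussianBlur(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]), sigma)
  (f - min(f)) / (max(f) - min(f) + 1e-12)
}

#' Generate a synthetic MSI phantom with planted isotope pairs
#'
#' Construction, all driven by per-channel substreams of \code{seed}:
#' \itemize{
#'   \item regions: thresholded smooth random fields (organ-like blobs);
#'   \item each clean ion image: a weighted sum of 1-3 region masks times a
#'     smooth intensity profile, max-normalized to [0, 1];
#'   \item monoisotopic noisy channel: clean times multiplicative lognormal
#'     noise, with \code{base_missing} of the support zeroed;
#'   \item isotopic noisy channel: \code{iso_abundance} times the same clean
#'     image times independent lognormal noise, with
#'     \code{base_missing + iso_extra_missing} of the support zeroed and
#'     \code{iso_outlier_frac} of the support replaced by outliers drawn
#'     uniformly from 2-4 times the channel maximum;
#'   \item m/z axis: monoisotopic slots spaced several Th apart with the
#'     isotopic partner at +1.003355 Th, so no spurious pair spacings arise.
#' }
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return a list with elements \code{noisy} (the degraded
#'   \code{MSIDataCube}), and \code{truth}: a list with \code{clean_cube}
#'   (noise-free, channels max-normalized; pure-noise channels all zero),
#'   \code{pair_manifest} (data.frame mono_channel, iso_channel),
#'   \code{region_masks} (list of logical matrices) and \code{channel_role}
#'   (character vector: mono/iso/unpaired/noise).
#' @export
generatePhantom <- function(config = phantomConfig()) {
  cfg <- config
  X <- cfg$shape[1]; Y <- cfg$shape[2]
  n_mol <- cfg$n_pairs + cfg$n_unpaired + cfg$n_noise_channels
  seeds <- deriveSeeds(cfg$seed, 4L + n_mol)

  regions <- withSeed(seeds[1], {
    lapply(seq_len(cfg$n_regions), function(i) {
      repeat {
        f <- smoothField(c(X, Y), sigma = max(X, Y) / 10)
        msk <- f > stats::quantile(f, stats::runif(1, 0.65, 0.8))
        if (sum(msk) >= 0.03 * X * Y) return(msk)
      }
    })
  })

  # m/z slots: molecules several Th apart; the only ~1.0034 Th spacings in
  # the axis are the planted mono -> iso gaps
  slot_mz <- withSeed(seeds[2], 300 + 6.5 * seq_len(n_mol) + stats::runif(n_mol, -1, 1))
  roles_mol <- c(
    rep("pair", cfg$n_pairs), rep("unpaired", cfg$n_unpaired),
    rep("noise", cfg$n_noise_channels)
  )
  roles_mol <- withSeed(seeds[3], sample(roles_mol))

  channel_mz <- numeric(); channel_role <- character()
  clean_list <- list(); noisy_list <- list()
  mono_of <- integer(); iso_of <- integer()

  si <- 4L
  for (m in seq_len(n_mol)) {
    si <- si + 1L
    role <- roles_mol[m]
    withSeed(seeds[si], {
      if (role == "noise") {
        # sparse salt noise, no spatial structure, low occupancy
        img <- matrix(0, X, Y)
        n_on <- round(0.03 * X * Y)
        img[sample.int(X * Y, n_on)] <- stats::runif(n_on, 0.2, 1)
        channel_mz <- c(channel_mz, slot_mz[m])
        channel_role <- c(channel_role, "noise")
        clean_list[[length(clean_list) + 1L]] <- matrix(0, X, Y)
        noisy_list[[length(noisy_list) + 1L]] <- img
      } else {
        k <- sample(1:3, 1)
        ridx <- sample(cfg$n_regions, k)
        w <- stats::runif(k, 0.3, 1)
        # multiplicative smooth profile: ion images span roughly an order of
        # magnitude within their support, as real MSI channels do
        profile <- exp(2.2 * (smoothField(c(X, Y), sigma = max(X, Y) / 12) - 0.5))
        clean <- matrix(0, X, Y)
        for (j in seq_len(k)) clean <- clean + w[j] * regions[[ridx[j]]]
        clean <- clean * profile
        if (max(clean) > 0) clean <- clean / max(clean)
        support <- which(clean > 0)

        degrade <- function(base, missing_frac, outlier_frac) {
          img <- base * exp(stats::rnorm(X * Y, 0, cfg$noise_sigma))
          sup <- intersect(which(base > 0), seq_len(X * Y))
          n_miss <- floor(missing_frac * length(sup))
          if (n_miss > 0) img[sample(sup, n_miss)] <- 0
          n_out <- floor(outlier_frac * length(sup))
          if (n_out > 0) {
            # anomalous-expression spikes: 2-4x the pixel's true intensity
            sel <- sample(sup, n_out)
            img[sel] <- stats::runif(n_out, 2, 4) * base[sel]
          }
          matrix(img, X, Y)
        }

        mono_noisy <- degrade(clean, cfg$base_missing, 0)
        channel_mz <- c(channel_mz, slot_mz[m])
        channel_role <- c(channel_role, if (role == "pair") "mono" else "unpaired")
        clean_list[[length(clean_list) + 1L]] <- clean
        noisy_list[[length(noisy_list) + 1L]] <- mono_noisy
        if (role == "pair") {
          iso_noisy <- degrade(
            cfg$iso_abundance * clean,
            cfg$base_missing + cfg$iso_extra_missing, cfg$iso_outlier_frac
          )
          mono_of <- c(mono_of, length(clean_list))
          channel_mz <- c(channel_mz, slot_mz[m] + C13_SPACING)
          channel_role <- c(channel_role, "iso")
          clean_list[[length(clean_list) + 1L]] <- clean
          noisy_list[[length(noisy_list) + 1L]] <- iso_noisy
          iso_of <- c(iso_of, length(clean_list))
        }
      }
    })
  }

  H <- length(channel_mz)
  if (H < 1L) stop("infeasible phantom config: no channels requested")
  ord <- order(channel_mz)
  rank <- match(seq_len(H), ord)

  toCube <- function(lst) {
    arr <- array(0, c(X, Y, H))
    for (k in seq_len(H)) arr[, , k] <- lst[[ord[k]]]
    arr
  }
  mask <- matrix(TRUE, X, Y)
  noisy <- MSIDataCube(toCube(noisy_list), channel_mz[ord], mask = mask,
    meta = list(phantom_seed = cfg$seed))
  clean <- MSIDataCube(toCube(clean_list), channel_mz[ord], mask = mask,
    meta = list(phantom_seed = cfg$seed, clean = TRUE))

  manifest <- data.frame(
    mono_channel = rank[mono_of],
    iso_channel = rank[iso_of]
  )
  list(
    noisy = noisy,
    truth = list(
      clean_cube = clean,
      pair_manifest = manifest,
      region_masks = regions,
      channel_role = channel_role[ord],
      config = cfg
    )
  )
}

#' Recall and precision of pair mining against the planted manifest
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{generatePhantom}}.
#' @param pairs a data.frame of mined pairs as returned by
#'   \code{\link{findIsotopePairs}}.
#' @return list with \code{recall}, \code{precision}, \code{n_reported},
#'   \code{n_manifest}, and \code{empty_report} (TRUE when no pairs were
#'   reported, in which case precision is 1 by convention).
#' @export
phantomReport <- function(truth, pairs) {
  manifest <- truth$pair_manifest
  key <- function(df) paste(df$mono_channel, df$iso_channel)
  n_rep <- nrow(pairs)
  n_man <- nrow(manifest)
  hits <- if (n_rep > 0) sum(key(pairs) %in% key(manifest)) else 0L
  list(
    recall = if (n_man > 0) hits / n_man else 1,
    precision = if (n_rep > 0) hits / n_rep else 1,
    n_reported = n_rep,
    n_manifest = n_man,
    empty_report = n_rep == 0L
  )
}
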