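#' Peak signal-to-noise ratio (PSNR)
#'
#' \code{10 * log10(data_range^2 / MSE)} with the mean squared error taken
#' over mask-true pixels. Identical images give \code{Inf}.
#'
#' @param test an \code{IonImage} or numeric matrix (the image under test).
#' @param ref the reference image, same shape.
#' @param data_range dynamic range of the data (default 1, the range
#'   guaranteed by preprocessing).
#' @param mask optional logical matrix; metric computed over TRUE pixels.
#' @return PSNR in dB (\code{Inf} when MSE is 0).
#' @export
psnr <- function(test, ref, data_range = 1.0, mask = NULL) {
  a <- asPixels(test); b <- asPixels(ref)
  if (!identical(dim(a), dim(b))) stop("psnr: image shapes differ")
  stopifnot(data_range > 0)
  mask <- resolveMask(a, mask)
  mse <- mean((a[mask] - b[mask])^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM in the convention of Wang et al.: a Gaussian weighting
#' window (11 x 11, sigma 1.5), stability constants K1 = 0.01 and K2 = 0.03,
#' population (not sample) covariance normalization. Local statistics are
#' computed by Gaussian filtering with edge-repeated reflective boundary
#' handling; a border strip of the window radius is discarded before
#' averaging. When a pixel mask is supplied it restricts the averaging, not
#' the filtering.
#'
#' @param test an \code{IonImage} or numeric matrix.
#' @param ref the reference image, same shape.
#' @param data_range dynamic range (default 1).
#' @param sigma Gaussian window standard deviation in pixels (default 1.5).
#' @param K1,K2 stability constants (defaults 0.01, 0.03).
#' @param mask optional logical matrix restricting the aggregation.
#' @return SSIM in [-1, 1]; identical images give 1.
#' @export
ssim <- function(test, ref, data_range = 1.0, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03, mask = NULL) {
  a <- asPixels(test); b <- asPixels(ref)
  if (!identical(dim(a), dim(b))) stop("ssim: image shapes differ")
  truncate <- 3.5  # gives an 11-tap window at sigma 1.5
  r <- as.integer(truncate * sigma + 0.5)
  win <- 2L * r + 1L
  if (any(dim(a) < win))
    stop(sprintf("ssim: image smaller than the %dx%d window", win, win))
  mask <- resolveMask(a, mask)

  blur <- function(m) gaussianBlur(m, sigma, truncate)
  ux <- blur(a); uy <- blur(b)
  uxx <- blur(a * a); uyy <- blur(b * b); uxy <- blur(a * b)
  vx <- uxx - ux * ux
  vy <- uyy - uy * uy
  vxy <- uxy - ux * uy

  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))

  inner_r <- (r + 1):(nrow(a) - r)
  inner_c <- (r + 1):(ncol(a) - r)
  S <- S[inner_r, inner_c]
  m <- mask[inner_r, inner_c]
  if (!any(m)) stop("ssim: no mask-true pixels inside the evaluation window")
  mean(S[m])
}

#' Evaluate denoising methods against a clean reference cube
#'
#' Computes per-channel PSNR and SSIM of each method's output against the
#' clean cube and aggregates mean and standard deviation across channels.
#'
#' @param clean the reference \code{MSIDataCube}.
#' @param denoised named list of \code{MSIDataCube}s, one per method (e.g.
#'   \code{list(noisy = ..., gaussian = ..., denoiser = ...)}).
#' @param data_range dynamic range for both metrics (default 1).
#' @return an \code{\linkS4class{EvalReport}}.
#' @export
evaluateMethods <- function(clean, denoised, data_range = 1.0) {
  stopifnot(is(clean, "MSIDataCube"), is.list(denoised), length(denoised) > 0,
    !is.null(names(denoised)), all(nzchar(names(denoised))))
  d <- dim(clean@intensities)
  H <- d[3]
  rows <- list()
  for (method in names(denoised)) {
    cube <- denoised[[method]]
    stopifnot(is(cube, "MSIDataCube"))
    if (!identical(dim(cube@intensities), d))
      stop("evaluateMethods: cube shape for method '", method,
        "' differs from the clean reference")
    for (k in seq_len(H)) {
      a <- cube@intensities[, , k]
      b <- clean@intensities[, , k]
      rows[[length(rows) + 1L]] <- data.frame(
        channel = k, mz = clean@mzAxis[k], method = method,
        psnr = psnr(a, b, data_range, mask = clean@pixelMask),
        ssim = ssim(a, b, data_range, mask = clean@pixelMask)
      )
    }
  }
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(names(denoised), function(method) {
    sub <- per[per$method == method, ]
    sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
    data.frame(
      method = method,
      mean_psnr = mean(sub$psnr), sd_psnr = sd0(sub$psnr),
      mean_ssim = mean(sub$ssim), sd_ssim = sd0(sub$ssim)
    )
  }))
  new("EvalReport", perChannel = per, aggregate = agg)
}

#' Access the per-channel table of an EvalReport
#' @param report an \code{EvalReport}.
#' @return data.frame (channel, mz, method, psnr, ssim).
#' @export
perChannel <- function(report) report@perChannel

#' Access the aggregate table of an EvalReport
#' @param report an \code{EvalReport}.
#' @return data.frame (method, mean_psnr, sd_psnr, mean_ssim, sd_ssim).
#' @export
aggregateReport <- function(report) report@aggregate
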