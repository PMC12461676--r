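# Classical denoising comparators: Gaussian filtering and wavelet shrinkage.

#' Baseline configuration
#'
#' @param gaussian_sigma standard deviation of the Gaussian filter in pixels
#'   (default 1).
#' @param wavelet_levels decomposition levels of the 2-D wavelet transform
#'   (default 3).
#' @return a validated list of class \code{BaselineConfig}. The wavelet is the
#'   orthogonal Daubechies-4 (8-tap) filter with periodized boundaries and
#'   universal soft thresholding.
#' @export
baselineConfig <- function(gaussian_sigma = 1.0, wavelet_levels = 3L) {
  stopifnot(gaussian_sigma > 0, wavelet_levels >= 1L)
  structure(
    list(gaussian_sigma = gaussian_sigma, wavelet_levels = as.integer(wavelet_levels)),
    class = c("BaselineConfig", "list")
  )
}

#' Gaussian filtering baseline
#'
#' 2-D Gaussian convolution with reflective boundary handling; the kernel is
#' normalized so total intensity is approximately preserved for
#' interior-supported images.
#'
#' @param image an \code{IonImage} or numeric matrix.
#' @param sigma filter standard deviation in pixels (default 1).
#' @return object of the same type as \code{image}.
#' @export
gaussianDenoise <- function(image, sigma = 1.0) {
  stopifnot(sigma > 0)
  px <- asPixels(image)
  likeInput(image, gaussianBlur(px, sigma))
}

# Daubechies-4 orthonormal scaling (low-pass) analysis filter; the wavelet
# filter is its quadrature mirror. Coefficients are the standard published
# values to full double precision.
DB4_LO <- c(
  -0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
  -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
  0.7148465705529157, 0.2303778133088965
)
DB4_HI <- rev(DB4_LO) * c(1, -1, 1, -1, 1, -1, 1, -1) * -1
# dec_hi[k] = (-1)^k dec_lo[L-1-k] (0-based): gives the standard QMF pairing

# One periodized analysis step along vector x (length even):
# a[k] = sum_m g[m] x[(2(k-1) + m) mod N], correlation + dyadic downsampling.
dwtStep1d <- function(x, g, h) {
  N <- length(x)
  idx <- outer(seq(0, N - 2, by = 2), seq_along(g) - 1L, `+`) %% N + 1L
  xm <- matrix(x[idx], nrow = N %/% 2L)
  list(a = as.vector(xm %*% g), d = as.vector(xm %*% h))
}

# Inverse of dwtStep1d: x[n] = sum_k a[k] g[(n - 2k) mod N] + d[k] h[...].
idwtStep1d <- function(a, d, g, h) {
  N <- 2L * length(a)
  x <- numeric(N)
  for (m in seq_along(g)) {
    pos <- (seq(0, N - 2, by = 2) + (m - 1L)) %% N + 1L
    contrib <- a * g[m] + d * h[m]
    x[pos] <- x[pos] + contrib
  }
  x
}

# Single-level 2-D periodized DWT: rows then columns.
dwt2 <- function(m, g = DB4_LO, h = DB4_HI) {
  nr <- nrow(m); nc <- ncol(m)
  lo <- matrix(0, nr, nc %/% 2L); hi <- matrix(0, nr, nc %/% 2L)
  for (i in seq_len(nr)) {
    s <- dwtStep1d(m[i, ], g, h)
    lo[i, ] <- s$a; hi[i, ] <- s$d
  }
  ll <- matrix(0, nr %/% 2L, nc %/% 2L); lh <- ll; hl <- ll; hh <- ll
  for (j in seq_len(nc %/% 2L)) {
    s <- dwtStep1d(lo[, j], g, h)
    ll[, j] <- s$a; hl[, j] <- s$d
    s <- dwtStep1d(hi[, j], g, h)
    lh[, j] <- s$a; hh[, j] <- s$d
  }
  list(ll = ll, lh = lh, hl = hl, hh = hh)
}

idwt2 <- function(cf, g = DB4_LO, h = DB4_HI) {
  nr2 <- nrow(cf$ll) * 2L; nc <- ncol(cf$ll)
  lo <- matrix(0, nr2, nc); hi <- matrix(0, nr2, nc)
  for (j in seq_len(nc)) {
    lo[, j] <- idwtStep1d(cf$ll[, j], cf$hl[, j], g, h)
    hi[, j] <- idwtStep1d(cf$lh[, j], cf$hh[, j], g, h)
  }
  out <- matrix(0, nr2, nc * 2L)
  for (i in seq_len(nr2)) {
    out[i, ] <- idwtStep1d(lo[i, ], hi[i, ], g, h)
  }
  out
}

softThreshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Wavelet shrinkage baseline
#'
#' Multilevel periodized 2-D Daubechies-4 transform; detail coefficients at
#' all levels are soft-thresholded at the universal threshold
#' \code{sigma_hat * sqrt(2 * log(n))}, with the noise scale
#' \code{sigma_hat} estimated as MAD/0.6745 of the finest-level diagonal
#' details; the reconstruction is clipped to nonnegative values.
#'
#' @param image an \code{IonImage} or numeric matrix; both dimensions must be
#'   divisible by \code{2^levels} and at least 16 pixels.
#' @param config a \code{\link{baselineConfig}} (only the wavelet settings
#'   are used).
#' @return object of the same type as \code{image}.
#' @export
waveletDenoise <- function(image, config = baselineConfig()) {
  px <- asPixels(image)
  levels <- config$wavelet_levels
  if (any(dim(px) < 16L) || any(dim(px) %% 2L^levels != 0))
    stop(sprintf(
      "waveletDenoise: image dims (%d x %d) must be >= 16 and divisible by 2^levels = %d",
      nrow(px), ncol(px), 2L^levels))
  n <- length(px)

  coeffs <- vector("list", levels)
  cur <- px
  for (l in seq_len(levels)) {
    cf <- dwt2(cur)
    coeffs[[l]] <- cf
    cur <- cf$ll
  }
  sigma_hat <- stats::median(abs(coeffs[[1]]$hh)) / 0.6745
  thr <- sigma_hat * sqrt(2 * log(n))

  for (l in seq_len(levels)) {
    coeffs[[l]]$lh <- softThreshold(coeffs[[l]]$lh, thr)
    coeffs[[l]]$hl <- softThreshold(coeffs[[l]]$hl, thr)
    coeffs[[l]]$hh <- softThreshold(coeffs[[l]]$hh, thr)
  }
  rec <- cur
  for (l in rev(seq_len(levels))) {
    coeffs[[l]]$ll <- rec
    rec <- idwt2(coeffs[[l]])
  }
  rec[rec < 0] <- 0
  likeInput(image, rec)
}

#' Apply a baseline denoiser to every channel of a cube
#'
#' @param cube an \code{MSIDataCube}.
#' @param method \code{"gaussian"} or \code{"wavelet"}.
#' @param config a \code{\link{baselineConfig}}.
#' @return the denoised cube (mask-false pixels forced to 0).
#' @export
baselineDenoiseCube <- function(cube, method = c("gaussian", "wavelet"),
                                config = baselineConfig()) {
  stopifnot(is(cube, "MSIDataCube"))
  method <- match.arg(method)
  H <- dim(cube@intensities)[3]
  for (k in seq_len(H)) {
    ch <- cube@intensities[, , k]
    ch <- if (method == "gaussian") gaussianDenoise(ch, config$gaussian_sigma)
      else waveletDenoise(ch, config)
    ch[!cube@pixelMask] <- 0
    cube@intensities[, , k] <- ch
  }
  cube@meta$denoised_by <- method
  cube
}
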