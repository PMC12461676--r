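# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Fan one seed out into n independent substream seeds, so consumers can add
# channels/stages without perturbing earlier streams.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Coerce an IonImage or matrix argument to a pixel matrix.
asPixels <- function(x) {
  if (is(x, "IonImage")) x@pixels
  else if (is.matrix(x)) x
  else stop("expected an IonImage or a numeric matrix")
}

# Re-wrap a pixel matrix in the same shape as the input argument.
likeInput <- function(x, pixels) {
  if (is(x, "IonImage"))
    new("IonImage", pixels = pixels, mz = x@mz, channelIndex = x@channelIndex)
  else pixels
}

# Default all-TRUE mask when none supplied.
resolveMask <- function(pixels, mask) {
  if (is.null(mask)) {
    array(TRUE, dim = dim(pixels))
  } else {
    stopifnot(identical(dim(mask), dim(pixels)))
    mask
  }
}

# 1-D Gaussian kernel matching the scipy.ndimage convention:
# radius = int(truncate * sigma + 0.5), weights exp(-x^2 / (2 sigma^2)),
# normalized to sum 1.
gaussianKernel1d <- function(sigma, truncate = 4.0) {
  r <- as.integer(truncate * sigma + 0.5)
  x <- (-r):r
  w <- exp(-0.5 * (x / sigma)^2)
  w / sum(w)
}

# Pad a matrix by `p` on each side, edge-repeated mirror ("reflect" in the
# scipy sense: d c b a | a b c d).
padReflect <- function(m, p) {
  n1 <- nrow(m); n2 <- ncol(m)
  ridx <- c(pmin(p:1, n1), 1:n1, pmax(n1 - (1:p) + 1L, 1L))
  cidx <- c(pmin(p:1, n2), 1:n2, pmax(n2 - (1:p) + 1L, 1L))
  m[ridx, cidx, drop = FALSE]
}

# Separable 2-D Gaussian blur with reflective boundary handling.
gaussianBlur <- function(m, sigma, truncate = 4.0) {
  k <- gaussianKernel1d(sigma, truncate)
  r <- (length(k) - 1L) %/% 2L
  mp <- padReflect(m, r)
  # rows
  out <- matrix(0, nrow(m), ncol(mp))
  for (i in seq_along(k))
    out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
  # cols
  res <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k))
    res <- res + k[i] * out[, i:(i + ncol(m) - 1L), drop = FALSE]
  res
}
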