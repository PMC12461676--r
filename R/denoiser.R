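# The denoising network f(. | theta): a U-Net-style convolutional
# encoder-decoder operating on single-channel ion images.
#
# Feature maps are 4-D arrays laid out (h, w, batch, channel): with R's
# column-major storage, reshaping to an (h*w*batch) x channel matrix is then
# a zero-copy dim change, which keeps the im2col convolution free of aperm
# transposes. Convolutions are 3x3, zero-padded 'same', computed as im2col
# followed by one BLAS matmul; weights are stored as (9 * Cin) x Cout
# matrices with rows grouped offset-major. Downsampling is 2x2 max pooling,
# upsampling is bilinear 2x (half-pixel aligned), skips are
# copy-and-concatenate. All of forward, backward and the Adam optimizer live
# here; training minimizes the mean absolute error between network output
# and the monoisotopic pseudo ground truth.

# -- tensor primitives --------------------------------------------------------

im2col3 <- function(X) {
  d <- dim(X)
  cpp_im2col3(X, d[1], d[2], d[3], d[4])
}

convForward <- function(X, W, b, k, return_cols = FALSE) {
  d <- dim(X); h <- d[1]; w <- d[2]; B <- d[3]; Cin <- d[4]
  Cout <- length(b)
  Xmat <- if (k == 1L) X else im2col3(X)
  if (k == 1L) dim(Xmat) <- c(h * w * B, Cin)
  Y <- Xmat %*% W
  if (any(b != 0)) Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(h, w, B, Cout)
  if (return_cols) list(Y = Y, Xcol = Xmat, dims = d) else Y
}

# Rows of W are grouped offset-major with channels fastest; the gradient
# w.r.t. the input of a 'same' zero-padded correlation is another 'same'
# correlation with the offset-flipped, channel-transposed weights.
flipTranspose <- function(W, Cin, Cout) {
  Warr <- array(W, c(Cin, 9L, Cout))
  Wf <- aperm(Warr[, 9:1, , drop = FALSE], c(3, 2, 1))
  dim(Wf) <- c(9L * Cout, Cin)
  Wf
}

# `Xcol` is the im2col matrix cached by the forward pass; `dims` the input
# tensor dims (h, w, B, Cin).
convBackward <- function(dY, Xcol, dims, W, k) {
  h <- dims[1]; w <- dims[2]; B <- dims[3]; Cin <- dims[4]
  Cout <- ncol(W)
  dYmat <- dY
  dim(dYmat) <- c(h * w * B, Cout)
  db <- colSums(dYmat)
  dW <- crossprod(Xcol, dYmat)
  if (k == 1L) {
    dX <- tcrossprod(dYmat, W)
    dim(dX) <- c(h, w, B, Cin)
  } else {
    dX <- convForward(dY, flipTranspose(W, Cin, Cout), numeric(Cin), 3L)
  }
  list(dX = dX, dW = dW, db = db)
}

reluForward <- function(X) {
  X[X < 0] <- 0
  X
}

maxpoolForward <- function(X, keep_cache = TRUE) {
  d <- dim(X); h <- d[1]; w <- d[2]
  i1 <- seq(1L, h, 2L); i2 <- seq(2L, h, 2L)
  j1 <- seq(1L, w, 2L); j2 <- seq(2L, w, 2L)
  x11 <- X[i1, j1, , , drop = FALSE]; x21 <- X[i2, j1, , , drop = FALSE]
  x12 <- X[i1, j2, , , drop = FALSE]; x22 <- X[i2, j2, , , drop = FALSE]
  Y <- pmax(x11, x21, x12, x22)
  if (!keep_cache) return(list(Y = Y))
  # route gradient to the first maximum in a fixed scan order
  m11 <- x11 == Y
  m21 <- (x21 == Y) & !m11
  m12 <- (x12 == Y) & !m11 & !m21
  m22 <- !m11 & !m21 & !m12
  list(Y = Y, masks = list(m11, m21, m12, m22))
}

maxpoolBackward <- function(dY, masks, h, w) {
  d <- dim(dY)
  dX <- array(0, c(h, w, d[3], d[4]))
  i1 <- seq(1L, h, 2L); i2 <- seq(2L, h, 2L)
  j1 <- seq(1L, w, 2L); j2 <- seq(2L, w, 2L)
  dX[i1, j1, , ] <- dY * masks[[1]]
  dX[i2, j1, , ] <- dY * masks[[2]]
  dX[i1, j2, , ] <- dY * masks[[3]]
  dX[i2, j2, , ] <- dY * masks[[4]]
  dX
}

# Bilinear 2x upsampling operator (half-pixel alignment), as an (2n x n)
# interpolation matrix applied to rows and columns.
upsampleMatrix <- function(n) {
  i <- 0:(2L * n - 1L)
  src <- pmin(pmax(i / 2 - 0.25, 0), n - 1L)
  l <- floor(src)
  f <- src - l
  M <- matrix(0, 2L * n, n)
  for (r in seq_along(i)) {
    M[r, l[r] + 1L] <- M[r, l[r] + 1L] + (1 - f[r])
    if (f[r] > 0) M[r, min(l[r] + 2L, n)] <- M[r, min(l[r] + 2L, n)] + f[r]
  }
  M
}

applySeparable <- function(X, Mr, Mc) {
  d <- dim(X)
  A <- array(Mr %*% matrix(X, nrow = d[1]), c(nrow(Mr), d[2], d[3], d[4]))
  A <- aperm(A, c(2, 1, 3, 4))
  Bv <- array(Mc %*% matrix(A, nrow = d[2]), c(nrow(Mc), nrow(Mr), d[3], d[4]))
  aperm(Bv, c(2, 1, 3, 4))
}

upsampleForward <- function(X, Uh, Uw) applySeparable(X, Uh, Uw)
upsampleBackward <- function(dY, Uh, Uw) applySeparable(dY, t(Uh), t(Uw))

# -- architecture -------------------------------------------------------------

archChannels <- function(baseChannels, depth) baseChannels * 2L^(0:(depth))

convLayerDims <- function(baseChannels, depth) {
  cc <- archChannels(baseChannels, depth)  # cc[l] = channels at level l
  dims <- list()
  cin <- 1L
  for (l in seq_len(depth)) {
    dims[[sprintf("enc%d_conv1", l)]] <- c(cin, cc[l])
    dims[[sprintf("enc%d_conv2", l)]] <- c(cc[l], cc[l])
    cin <- cc[l]
  }
  dims[["bott_conv1"]] <- c(cc[depth], cc[depth + 1L])
  dims[["bott_conv2"]] <- c(cc[depth + 1L], cc[depth + 1L])
  for (l in rev(seq_len(depth))) {
    dims[[sprintf("dec%d_conv1", l)]] <- c(cc[l] + cc[l + 1L], cc[l])
    dims[[sprintf("dec%d_conv2", l)]] <- c(cc[l], cc[l])
  }
  dims[["final"]] <- c(cc[1], 1L)
  dims
}

#' Build an untrained denoiser model
#'
#' Constructs the encoder-decoder network: per encoder level two 3x3
#' convolutions with ReLU then 2x2 max pooling, channels doubling from
#' \code{baseChannels}; a two-convolution bottleneck at
#' \code{baseChannels * 2^depth}; a mirrored decoder with bilinear 2x
#' upsampling and copy-and-concatenate skip connections; and a final linear
#' 1x1 convolution to one channel. Weights are drawn from N(0, init_sd^2),
#' biases start at zero.
#'
#' @param baseChannels channels of the first encoder level (default 64; the
#'   desk-scale preset uses 16).
#' @param depth number of pooling levels (default 4, reaching
#'   \code{baseChannels * 2^4} bottleneck channels).
#' @param init_sd standard deviation of the \code{"normal"} weight
#'   initializer (default 0.02).
#' @param init \code{"normal"}: all weights N(0, init_sd^2) — adequate at the
#'   full-scale width of 64 base channels; \code{"he"}: fan-in-scaled
#'   N(0, 2/fan_in), which keeps ReLU activations alive at the narrow
#'   desk-scale widths where the flat-variance init frequently yields a dead
#'   network under the MAE objective.
#' @param seed RNG seed for the initializer; two builds with the same seed
#'   have identical weights.
#' @return a \code{\linkS4class{DenoiserModel}}.
#' @examples
#' m <- buildDenoiser(baseChannels = 8, depth = 2, seed = 1)
#' @export
buildDenoiser <- function(baseChannels = 64L, depth = 4L, init_sd = 0.02,
                          init = c("normal", "he"), seed = 0L) {
  stopifnot(baseChannels >= 1L, depth >= 1L, init_sd > 0)
  init <- match.arg(init)
  dims <- convLayerDims(as.integer(baseChannels), as.integer(depth))
  params <- withSeed(seed, {
    lapply(names(dims), function(nm) {
      io <- dims[[nm]]
      k <- if (nm == "final") 1L else 3L
      sd <- if (init == "he") sqrt(2 / (k * k * io[1])) else init_sd
      list(
        W = matrix(stats::rnorm(k * k * io[1] * io[2], 0, sd),
          k * k * io[1], io[2]),
        b = numeric(io[2]), k = k, cin = io[1], cout = io[2]
      )
    })
  })
  names(params) <- names(dims)
  new("DenoiserModel",
    params = params,
    arch = list(baseChannels = as.integer(baseChannels),
      depth = as.integer(depth), kernel = 3L, init_sd = init_sd,
      init = init, init_seed = as.integer(seed)),
    trainConfig = list(), history = numeric(), valHistory = numeric()
  )
}

# Forward pass through the network. Returns the output tensor and, when
# `keep_cache`, everything backward needs.
netForward <- function(params, arch, X, keep_cache = FALSE) {
  depth <- arch$depth
  cache <- list(inputs = list(), pools = list(), skips = list(), ups = list())
  cur <- X
  convRelu <- function(nm, cur) {
    if (keep_cache) {
      fw <- convForward(cur, params[[nm]]$W, params[[nm]]$b, params[[nm]]$k,
        return_cols = TRUE)
      cache$inputs[[nm]] <<- list(Xcol = fw$Xcol, dims = fw$dims)
      cache[[paste0(nm, "_pre")]] <<- fw$Y
      reluForward(fw$Y)
    } else {
      reluForward(convForward(cur, params[[nm]]$W, params[[nm]]$b, params[[nm]]$k))
    }
  }
  for (l in seq_len(depth)) {
    cur <- convRelu(sprintf("enc%d_conv1", l), cur)
    cur <- convRelu(sprintf("enc%d_conv2", l), cur)
    cache$skips[[l]] <- cur
    mp <- maxpoolForward(cur, keep_cache)
    if (keep_cache) cache$pools[[l]] <- list(masks = mp$masks, h = dim(cur)[1], w = dim(cur)[2])
    cur <- mp$Y
  }
  cur <- convRelu("bott_conv1", cur)
  cur <- convRelu("bott_conv2", cur)
  for (l in rev(seq_len(depth))) {
    hh <- dim(cur)[1]; ww <- dim(cur)[2]
    Uh <- upsampleMatrix(hh); Uw <- upsampleMatrix(ww)
    if (keep_cache) cache$ups[[l]] <- list(Uh = Uh, Uw = Uw)
    up <- upsampleForward(cur, Uh, Uw)
    skip <- cache$skips[[l]]
    nskip <- dim(skip)[4]
    cur <- array(0, c(dim(up)[1], dim(up)[2], dim(up)[3], nskip + dim(up)[4]))
    cur[, , , seq_len(nskip)] <- skip
    cur[, , , nskip + seq_len(dim(up)[4])] <- up
    if (keep_cache) cache[[sprintf("dec%d_nskip", l)]] <- nskip
    cur <- convRelu(sprintf("dec%d_conv1", l), cur)
    cur <- convRelu(sprintf("dec%d_conv2", l), cur)
  }
  if (keep_cache) {
    fw <- convForward(cur, params[["final"]]$W, params[["final"]]$b, 1L,
      return_cols = TRUE)
    cache$inputs[["final"]] <- list(Xcol = fw$Xcol, dims = fw$dims)
    out <- fw$Y
  } else {
    out <- convForward(cur, params[["final"]]$W, params[["final"]]$b, 1L)
  }
  list(out = out, cache = cache)
}

# Backward pass; returns gradients for every layer, keyed like params.
netBackward <- function(params, arch, cache, dOut) {
  depth <- arch$depth
  grads <- list()
  convReluBack <- function(nm, dY) {
    dPre <- dY * (cache[[paste0(nm, "_pre")]] > 0)
    inp <- cache$inputs[[nm]]
    g <- convBackward(dPre, inp$Xcol, inp$dims, params[[nm]]$W, params[[nm]]$k)
    grads[[nm]] <<- list(dW = g$dW, db = g$db)
    g$dX
  }
  inpF <- cache$inputs[["final"]]
  g <- convBackward(dOut, inpF$Xcol, inpF$dims, params[["final"]]$W, 1L)
  grads[["final"]] <- list(dW = g$dW, db = g$db)
  cur <- g$dX
  for (l in seq_len(depth)) {
    cur <- convReluBack(sprintf("dec%d_conv2", l), cur)
    cur <- convReluBack(sprintf("dec%d_conv1", l), cur)
    nskip <- cache[[sprintf("dec%d_nskip", l)]]
    dSkip <- cur[, , , seq_len(nskip), drop = FALSE]
    dUp <- cur[, , , nskip + seq_len(dim(cur)[4] - nskip), drop = FALSE]
    cur <- upsampleBackward(dUp, cache$ups[[l]]$Uh, cache$ups[[l]]$Uw)
    # stash the skip gradient until the encoder pass reaches this level
    grads[[sprintf("skipgrad%d", l)]] <- dSkip
  }
  cur <- convReluBack("bott_conv2", cur)
  cur <- convReluBack("bott_conv1", cur)
  for (l in rev(seq_len(depth))) {
    pl <- cache$pools[[l]]
    cur <- maxpoolBackward(cur, pl$masks, pl$h, pl$w)
    cur <- cur + grads[[sprintf("skipgrad%d", l)]]
    grads[[sprintf("skipgrad%d", l)]] <- NULL
    cur <- convReluBack(sprintf("enc%d_conv2", l), cur)
    cur <- convReluBack(sprintf("enc%d_conv1", l), cur)
  }
  grads
}

#' Mean absolute error reconstruction loss
#'
#' \code{L_rec = (1/N) * sum_i mean(|target_i - output_i|)}: the inner mean
#' runs over pixels of pair i, the outer over the N pairs of the batch.
#'
#' @param outputs list of numeric matrices (network outputs), or a 3-D/4-D
#'   array whose last dimension indexes pairs.
#' @param targets matching list/array of target images.
#' @return nonnegative scalar; 0 iff outputs equal targets.
#' @export
reconstructionLoss <- function(outputs, targets) {
  toList <- function(x) {
    if (is.list(x)) lapply(x, asPixels)
    else if (is.array(x) && length(dim(x)) >= 3L) {
      nd <- length(dim(x))
      apply(x, nd, identity, simplify = FALSE)
    } else list(asPixels(x))
  }
  o <- toList(outputs); tg <- toList(targets)
  if (length(o) != length(tg)) stop("reconstructionLoss: batch sizes differ")
  if (length(o) == 0L) stop("reconstructionLoss: empty batch")
  per <- vapply(seq_along(o), function(i) {
    if (length(o[[i]]) != length(tg[[i]]))
      stop("reconstructionLoss: shape mismatch in pair ", i)
    mean(abs(tg[[i]] - o[[i]]))
  }, numeric(1))
  mean(per)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 0.005 and default momentum parameters, weights initialized N(0, 0.02),
#' batch size 256 (whole ion images per batch element), 20000 epochs. The
#' desk-scale preset (\code{\link{deskPreset}}) is what the package's own
#' experiments use.
#'
#' @param learning_rate Adam step size (default 0.005).
#' @param batch_size pairs per minibatch (default 256).
#' @param epochs training epochs (default 20000).
#' @param val_fraction fraction of pairs held out to select the best
#'   checkpoint (default 0.1; with fewer than 10 pairs the training loss is
#'   used instead).
#' @param seed RNG seed governing the split and shuffling.
#' @param beta1,beta2,eps Adam moment parameters (defaults 0.9, 0.999, 1e-8).
#' @return a validated list of class \code{TrainConfig}.
#' @export
trainConfig <- function(learning_rate = 0.005, batch_size = 256L,
                        epochs = 20000L, val_fraction = 0.1, seed = 0L,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L,
    val_fraction >= 0, val_fraction < 1)
  structure(
    list(
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      epochs = as.integer(epochs), val_fraction = val_fraction,
      seed = as.integer(seed), beta1 = beta1, beta2 = beta2, eps = eps
    ),
    class = c("TrainConfig", "list")
  )
}

#' Desk-scale preset: architecture and training settings for CPU-scale runs
#'
#' @param epochs training epochs (default 300).
#' @param seed RNG seed.
#' @return list with \code{baseChannels}, \code{depth} and a
#'   \code{\link{trainConfig}}.
#' @export
deskPreset <- function(epochs = 300L, seed = 0L) {
  list(baseChannels = 16L, depth = 3L, init = "he",
    train = trainConfig(epochs = epochs, seed = seed))
}

#' Full-scale preset mirroring the reference recipe
#'
#' @param seed RNG seed.
#' @return list with \code{baseChannels = 64}, \code{depth = 4} and the
#'   default \code{\link{trainConfig}} (20000 epochs).
#' @export
paperPreset <- function(seed = 0L) {
  list(baseChannels = 64L, depth = 4L, init = "normal",
    train = trainConfig(seed = seed))
}

# stack single-channel images into an (h, w, batch, 1) tensor
stackBatch <- function(imgs) {
  d <- dim(imgs[[1]])
  X <- array(0, c(d[1], d[2], length(imgs), 1L))
  for (i in seq_along(imgs)) X[, , i, 1L] <- imgs[[i]]
  X
}

#' Train the denoiser on mined ion-image pairs
#'
#' Minimizes the mean absolute error between network outputs on isotopic
#' inputs and their monoisotopic targets with Adam. A validation split
#' selects the checkpoint with the lowest validation loss, which is the model
#' returned; the full per-epoch loss history is recorded.
#'
#' @param model an untrained (or pre-trained) \code{DenoiserModel}.
#' @param training_set list of (input, target) pairs from
#'   \code{\link{buildTrainingSet}}; image dims must be divisible by
#'   \code{2^depth}.
#' @param config a \code{\link{trainConfig}}.
#' @return the trained \code{DenoiserModel} with \code{history} and
#'   \code{valHistory} filled in.
#' @export
trainDenoiser <- function(model, training_set, config = trainConfig()) {
  stopifnot(is(model, "DenoiserModel"))
  N <- length(training_set)
  if (N < 2L) stop("trainDenoiser: need at least 2 pairs")
  d <- dim(asPixels(training_set[[1]]$input))
  if (any(d %% 2L^model@arch$depth != 0))
    stop(sprintf("trainDenoiser: image dims (%d x %d) must be divisible by 2^depth = %d",
      d[1], d[2], 2L^model@arch$depth))

  X <- stackBatch(lapply(training_set, function(p) asPixels(p$input)))
  T_ <- stackBatch(lapply(training_set, function(p) asPixels(p$target)))

  n_val <- floor(config$val_fraction * N)
  idx <- withSeed(config$seed, sample.int(N))
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer()
  tr_idx <- setdiff(idx, val_idx)
  if (length(tr_idx) < 1L) stop("trainDenoiser: no training pairs left after split")

  params <- model@params
  adam_m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  adam_v <- adam_m
  t_step <- 0
  lr <- config$learning_rate; b1 <- config$beta1; b2 <- config$beta2
  eps <- config$eps

  epoch_seeds <- deriveSeeds(config$seed + 1L, config$epochs)
  history <- numeric(config$epochs)
  val_history <- numeric(config$epochs)
  best_val <- Inf
  best_params <- params

  Xval <- if (n_val > 0) X[, , val_idx, , drop = FALSE]
  Tval <- if (n_val > 0) T_[, , val_idx, , drop = FALSE]

  for (ep in seq_len(config$epochs)) {
    ord <- if (length(tr_idx) > config$batch_size)
      withSeed(epoch_seeds[ep], sample(tr_idx)) else tr_idx
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      Xb <- X[, , bt, , drop = FALSE]
      Tb <- T_[, , bt, , drop = FALSE]
      fw <- netForward(params, model@arch, Xb, keep_cache = TRUE)
      resid <- fw$out - Tb
      loss <- mean(abs(resid))
      if (!is.finite(loss))
        stop(sprintf("trainDenoiser: non-finite loss at epoch %d (diverged; lower the learning rate)", ep))
      ep_loss <- ep_loss + loss * length(bt)
      dOut <- sign(resid) / length(resid)
      grads <- netBackward(params, model@arch, fw$cache, dOut)
      t_step <- t_step + 1
      corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
      for (nm in names(params)) {
        g <- grads[[nm]]
        adam_m[[nm]]$W <- b1 * adam_m[[nm]]$W + (1 - b1) * g$dW
        adam_v[[nm]]$W <- b2 * adam_v[[nm]]$W + (1 - b2) * g$dW^2
        params[[nm]]$W <- params[[nm]]$W -
          lr * corr * adam_m[[nm]]$W / (sqrt(adam_v[[nm]]$W) + eps)
        adam_m[[nm]]$b <- b1 * adam_m[[nm]]$b + (1 - b1) * g$db
        adam_v[[nm]]$b <- b2 * adam_v[[nm]]$b + (1 - b2) * g$db^2
        params[[nm]]$b <- params[[nm]]$b -
          lr * corr * adam_m[[nm]]$b / (sqrt(adam_v[[nm]]$b) + eps)
      }
    }
    history[ep] <- ep_loss / length(ord)
    if (n_val > 0) {
      vout <- netForward(params, model@arch, Xval)$out
      val_history[ep] <- mean(abs(vout - Tval))
    } else {
      val_history[ep] <- history[ep]
    }
    if (val_history[ep] < best_val) {
      best_val <- val_history[ep]
      best_params <- params
    }
  }

  model@params <- best_params
  model@trainConfig <- unclass(config)
  model@history <- history
  model@valHistory <- val_history
  model
}

# Reflect-pad a matrix on the bottom/right so both dims are multiples of m.
padToMultiple <- function(px, m) {
  h <- nrow(px); w <- ncol(px)
  H <- as.integer(ceiling(h / m) * m)
  W <- as.integer(ceiling(w / m) * m)
  if (H - h >= h || W - w >= w)
    stop(sprintf("image (%d x %d) too small to pad to a multiple of %d", h, w, m))
  ridx <- c(1:h, h - seq_len(H - h))
  cidx <- c(1:w, w - seq_len(W - w))
  px[ridx, cidx, drop = FALSE]
}

#' Run a single ion image through the denoiser
#'
#' Images whose dims are not multiples of \code{2^depth} are reflect-padded
#' before the forward pass and cropped after; outputs are clipped to
#' nonnegative values.
#'
#' @param model a trained \code{DenoiserModel}.
#' @param image an \code{IonImage} or numeric matrix in [0, 1].
#' @return object of the same type as \code{image}.
#' @export
denoiseImage <- function(model, image) {
  px <- asPixels(image)
  m <- 2L^model@arch$depth
  padded <- padToMultiple(px, m)
  X <- array(padded, c(nrow(padded), ncol(padded), 1L, 1L))
  out <- netForward(model@params, model@arch, X)$out[, , 1L, 1L]
  out <- out[seq_len(nrow(px)), seq_len(ncol(px)), drop = FALSE]
  out[out < 0] <- 0
  likeInput(image, out)
}

#' Denoise every channel of a datacube
#'
#' All H channels (paired or not) are passed through the trained network in
#' batches; outputs are clipped to nonnegative values and mask-false pixels
#' forced to zero. The m/z axis and mask are carried over unchanged.
#'
#' @param model a trained \code{DenoiserModel}.
#' @param cube a preprocessed \code{MSIDataCube} (channels in [0, 1]).
#' @param batch_size channels per forward batch (default 32).
#' @return the denoised \code{MSIDataCube}.
#' @export
denoiseCube <- function(model, cube, batch_size = 32L) {
  stopifnot(is(model, "DenoiserModel"), is(cube, "MSIDataCube"))
  d <- dim(cube@intensities)
  m <- 2L^model@arch$depth
  padded1 <- padToMultiple(cube@intensities[, , 1], m)
  hp <- nrow(padded1); wp <- ncol(padded1)
  out <- cube@intensities
  for (start in seq(1L, d[3], by = batch_size)) {
    ks <- start:min(start + batch_size - 1L, d[3])
    X <- array(0, c(hp, wp, length(ks), 1L))
    for (i in seq_along(ks))
      X[, , i, 1L] <- padToMultiple(cube@intensities[, , ks[i]], m)
    Y <- netForward(model@params, model@arch, X)$out
    for (i in seq_along(ks)) {
      ch <- Y[seq_len(d[1]), seq_len(d[2]), i, 1L]
      ch[ch < 0] <- 0
      ch[!cube@pixelMask] <- 0
      out[, , ks[i]] <- ch
    }
  }
  cube@intensities <- out
  cube@meta$denoised_by <- "denoiser"
  cube
}
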