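test_that("reconstruction loss equals the brute-force elementwise oracle", {
  set.seed(51)
  # independent oracle: per-pair mean absolute difference, averaged over pairs
  bruteForce <- function(os, ts) {
    tot <- 0
    for (i in seq_along(os)) tot <- tot + sum(abs(ts[[i]] - os[[i]])) / length(os[[i]])
    tot / length(os)
  }
  for (rep in 1:5) {
    os <- replicate(4, matrix(runif(12 * 9), 12), simplify = FALSE)
    ts <- replicate(4, matrix(runif(12 * 9), 12), simplify = FALSE)
    expect_equal(reconstructionLoss(os, ts), bruteForce(os, ts), tolerance = 1e-7)
  }
  a <- matrix(0.5, 6, 6)
  expect_equal(reconstructionLoss(list(a), list(a)), 0)
  expect_equal(reconstructionLoss(list(matrix(0, 6, 6)), list(a)), 0.5)
  expect_error(reconstructionLoss(list(a), list(matrix(1, 2, 2))), "mismatch")
  expect_error(reconstructionLoss(list(), list()), "empty")
})

test_that("network forward pass preserves spatial dimensions", {
  m <- buildDenoiser(baseChannels = 4, depth = 2, seed = 1)
  for (sz in list(c(16, 16), c(32, 24), c(64, 64))) {
    img <- matrix(runif(prod(sz)), sz[1], sz[2])
    out <- denoiseImage(m, img)
    expect_equal(dim(out), sz)
    expect_true(all(out >= 0))
  }
})

test_that("odd-sized inputs are reflect-padded then cropped", {
  m <- buildDenoiser(baseChannels = 8, depth = 2, seed = 2)
  img <- matrix(runif(33 * 47), 33, 47)
  out <- denoiseImage(m, img)
  expect_equal(dim(out), c(33L, 47L))
})

test_that("two builds with the same seed have identical parameters", {
  a <- buildDenoiser(8, 2, seed = 7)
  b <- buildDenoiser(8, 2, seed = 7)
  expect_identical(a@params, b@params)
  c <- buildDenoiser(8, 2, seed = 8)
  expect_false(identical(a@params, c@params))
  # N(0, 0.02) initialization, biases zero
  w <- unlist(lapply(a@params, `[[`, "W"))
  expect_equal(sd(w), 0.02, tolerance = 0.01)
  expect_true(all(unlist(lapply(a@params, `[[`, "b")) == 0))
})

test_that("analytic gradients match finite differences on a tiny network", {
  nf <- MSIdenoise:::netForward; nb <- MSIdenoise:::netBackward
  set.seed(52)
  # a larger-scale init keeps pre-activations away from the ReLU kink, where
  # finite differences would disagree with one-sided analytic gradients
  m <- buildDenoiser(3, 2, init_sd = 0.5, seed = 9)
  X <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  T_ <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  # squared loss keeps the objective differentiable for the check
  lossOf <- function(params) sum((nf(params, m@arch, X)$out - T_)^2)
  fw <- nf(m@params, m@arch, X, keep_cache = TRUE)
  grads <- nb(m@params, m@arch, fw$cache, 2 * (fw$out - T_))
  eps <- 1e-6
  for (nm in names(m@params)) {
    ii <- sample(length(m@params[[nm]]$W), min(4, length(m@params[[nm]]$W)))
    for (i in ii) {
      p <- m@params
      p[[nm]]$W[i] <- p[[nm]]$W[i] + eps; up <- lossOf(p)
      p[[nm]]$W[i] <- p[[nm]]$W[i] - 2 * eps; dn <- lossOf(p)
      expect_equal(grads[[nm]]$dW[i], (up - dn) / (2 * eps), tolerance = 1e-3)
    }
    p <- m@params
    p[[nm]]$b[1] <- p[[nm]]$b[1] + eps; up <- lossOf(p)
    p[[nm]]$b[1] <- p[[nm]]$b[1] - 2 * eps; dn <- lossOf(p)
    expect_equal(grads[[nm]]$db[1], (up - dn) / (2 * eps), tolerance = 1e-3)
  }
})

test_that("training reduces the loss and records a full history", {
  ph <- smallPhantom(seed = 53)
  prep <- preprocessCube(ph$noisy)
  tset <- buildTrainingSet(prep, findIsotopePairs(prep))
  m <- buildDenoiser(16, 2, init = "he", seed = 3)
  fit <- trainDenoiser(m, tset, trainConfig(epochs = 100, seed = 3))
  expect_length(fit@history, 100)
  expect_length(fit@valHistory, 100)
  expect_lt(min(fit@history), fit@history[1])
  expect_lt(mean(tail(fit@history, 10)), mean(head(fit@history, 10)))
  expect_error(trainDenoiser(m, tset[1], trainConfig(epochs = 1)), "at least 2")
})

test_that("training is reproducible for a fixed seed", {
  ph <- smallPhantom(seed = 54)
  prep <- preprocessCube(ph$noisy)
  tset <- buildTrainingSet(prep, findIsotopePairs(prep))
  cfg <- trainConfig(epochs = 8, seed = 11)
  a <- trainDenoiser(buildDenoiser(4, 2, seed = 4), tset, cfg)
  b <- trainDenoiser(buildDenoiser(4, 2, seed = 4), tset, cfg)
  expect_identical(a@history, b@history)
  expect_identical(a@params, b@params)
})

test_that("the network learns the identity on smooth images", {
  ph <- generatePhantom(phantomConfig(seed = 55, shape = c(32L, 32L),
    n_pairs = 10L))
  clean <- intensityArray(ph$truth$clean_cube)
  roles <- ph$truth$channel_role
  ch <- which(roles == "mono")[1:10]
  tset <- lapply(ch, function(k)
    list(input = clean[, , k], target = clean[, , k]))
  m <- buildDenoiser(16, 2, init = "he", seed = 5)
  fit <- trainDenoiser(m, tset, trainConfig(epochs = 100, seed = 5))
  expect_lt(min(fit@valHistory), 0.02)
})

test_that("denoiseCube processes every channel and respects the mask", {
  ph <- smallPhantom(seed = 56)
  prep <- preprocessCube(ph$noisy)
  tset <- buildTrainingSet(prep, findIsotopePairs(prep))
  m <- trainDenoiser(buildDenoiser(16, 2, init = "he", seed = 6), tset,
    trainConfig(epochs = 40, seed = 6))
  out <- denoiseCube(m, prep)
  expect_equal(dim(out), dim(prep))
  expect_identical(mzAxis(out), mzAxis(prep))
  expect_true(all(intensityArray(out) >= 0))
  # an all-zero channel maps to (near-)zero output
  z <- denoiseImage(m, matrix(0, 32, 32))
  expect_lt(max(z), 0.05)
})
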