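test_that("psnr matches its closed form and handles the zero-MSE sentinel", {
  a <- matrix(0.5, 4, 4)
  expect_identical(psnr(a, a), Inf)
  # MSE 0.01 at range 1 -> exactly 20 dB
  b <- a + 0.1
  expect_equal(psnr(b, a), 20)
  expect_error(psnr(matrix(1, 2, 2), matrix(1, 3, 3)), "shapes differ")
  # mask restricts the average
  ref <- matrix(0, 2, 2)
  tst <- matrix(c(0.1, 0, 0, 0), 2, 2)
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(psnr(tst, ref, mask = mask), 10 * log10(1 / 0.01))
})

test_that("ssim is 1 for identical images and symmetric", {
  set.seed(21)
  a <- matrix(runif(32 * 32), 32)
  expect_equal(ssim(a, a), 1)
  b <- matrix(runif(32 * 32), 32)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-9)
  expect_error(ssim(matrix(1, 8, 8), matrix(1, 8, 8)), "smaller than")
})

test_that("contrast inversion drives ssim well below 1", {
  set.seed(22)
  a <- matrix(0, 32, 32)
  a[8:24, 8:24] <- 0.8
  a <- a + matrix(runif(1024, 0, 0.1), 32)
  expect_lt(ssim(1 - a, a), 0.5)
})

test_that("psnr decreases monotonically with noise amplitude", {
  set.seed(23)
  img <- matrix(runif(40 * 40), 40)
  noise <- matrix(rnorm(1600), 40)
  p <- sapply(c(0.05, 0.15, 0.45), function(amp) {
    noisy <- pmin(pmax(img + amp * noise, 0), 1)
    psnr(noisy, img)
  })
  expect_true(all(diff(p) < 0))
  s <- sapply(c(0.05, 0.15, 0.45), function(amp) {
    noisy <- pmin(pmax(img + amp * noise, 0), 1)
    ssim(noisy, img)
  })
  expect_true(all(diff(s) < 0))
})

test_that("psnr and ssim agree with the scikit-image reference on random pairs", {
  set.seed(24)
  n <- 20
  tests <- replicate(n, matrix(runif(28 * 33), 28, 33), simplify = FALSE)
  refs <- replicate(n, matrix(runif(28 * 33), 28, 33), simplify = FALSE)
  oracle <- metricsOracle(tests, refs)
  for (i in seq_len(n)) {
    expect_equal(psnr(tests[[i]], refs[[i]]), oracle$psnr[i], tolerance = 1e-8)
    expect_equal(ssim(tests[[i]], refs[[i]]), oracle$ssim[i], tolerance = 1e-8)
  }
})

test_that("evaluateMethods reproduces hand-computed values on a toy cube", {
  set.seed(25)
  arr <- array(runif(16 * 16 * 2), c(16, 16, 2))
  clean <- MSIDataCube(arr, mz = c(100, 200))
  noisy_arr <- pmin(pmax(arr + array(rnorm(512, 0, 0.1), dim(arr)), 0), 1)
  noisy <- MSIDataCube(noisy_arr, mz = c(100, 200))
  rep <- evaluateMethods(clean, list(self = clean, noisy = noisy))
  agg <- aggregateReport(rep)
  # method output == clean: sentinel-Inf PSNR, SSIM exactly 1
  expect_identical(agg$mean_psnr[agg$method == "self"], Inf)
  expect_equal(agg$mean_ssim[agg$method == "self"], 1)
  # per-channel values match direct metric calls
  pc <- perChannel(rep)
  for (k in 1:2) {
    expect_equal(pc$psnr[pc$method == "noisy" & pc$channel == k],
      psnr(noisy_arr[, , k], arr[, , k]))
    expect_equal(pc$ssim[pc$method == "noisy" & pc$channel == k],
      ssim(noisy_arr[, , k], arr[, , k]))
  }
  # aggregates are means/sds over channels
  sub <- pc[pc$method == "noisy", ]
  expect_equal(agg$mean_psnr[agg$method == "noisy"], mean(sub$psnr))
  expect_equal(agg$sd_psnr[agg$method == "noisy"], sd(sub$psnr))
})

test_that("single-channel aggregation reports the value itself with sd 0", {
  arr <- array(runif(16 * 16), c(16, 16, 1))
  clean <- MSIDataCube(arr, mz = 100)
  noisy <- MSIDataCube(pmin(arr + 0.05, 1), mz = 100)
  rep <- evaluateMethods(clean, list(m = noisy))
  agg <- aggregateReport(rep)
  expect_equal(agg$sd_psnr, 0)
  expect_equal(agg$mean_psnr, perChannel(rep)$psnr)
  # shape mismatch is rejected
  bad <- MSIDataCube(array(1, c(8, 8, 1)), mz = 100)
  expect_error(evaluateMethods(clean, list(m = bad)), "shape")
})
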