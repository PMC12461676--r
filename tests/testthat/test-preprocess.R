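test_that("TIC normalization makes nonzero pixel spectra sum to one", {
  arr <- array(0, c(2, 1, 3))
  arr[1, 1, ] <- c(2, 2, 4)
  cube <- MSIDataCube(arr, mz = c(100, 200, 300))
  out <- ticNormalize(cube)
  expect_equal(intensityArray(out)[1, 1, ], c(0.25, 0.25, 0.5))
  # all-zero pixel untouched
  expect_equal(intensityArray(out)[2, 1, ], c(0, 0, 0))

  cube <- randomCube(9, 7, 12, seed = 4)
  out <- ticNormalize(cube)
  sums <- apply(intensityArray(out), c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("hotspot truncation clips strictly above q times the max", {
  expect_equal(as.vector(truncateHotspots(matrix(c(0, 0.5, 1.0), 1), q = 0.99)),
    c(0, 0.5, 0.99))
  # constant image: every pixel exceeds 0.99 * max, so all become 0.99c
  expect_equal(as.vector(truncateHotspots(matrix(2, 2, 2), q = 0.99)),
    rep(1.98, 4))
  # q = 1 is the identity
  m <- matrix(runif(25), 5)
  expect_equal(truncateHotspots(m, q = 1), m)
  # all-zero image unchanged
  z <- matrix(0, 3, 3)
  expect_equal(truncateHotspots(z), z)
  # ties at the threshold are kept (strict inequality)
  m2 <- matrix(c(0.99, 1), 1)
  expect_equal(as.vector(truncateHotspots(m2, 0.99)), c(0.99, 0.99))
})

test_that("hotspot truncation re-application only rescales the clipped plateau", {
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(rexp(64), 8)
    once <- truncateHotspots(m, 0.99)
    twice <- truncateHotspots(once, 0.99)
    # the literal exceed-q-of-max rule composes to a clip at q^2 * max: a
    # second application lowers the ceiling but is the identity below it
    expect_equal(twice, pmin(once, 0.99^2 * max(m)))
    expect_equal(max(twice), 0.99 * max(once))
    # order preservation
    o <- order(m)
    expect_true(all(diff(once[o]) >= -1e-12))
  }
  # when nothing exceeds the threshold the operator is the identity
  flat <- matrix(seq(0, 0.9, length.out = 16), 4)
  flat[16] <- 10  # single spike far above the rest
  once <- truncateHotspots(flat, 0.99)
  expect_equal(sum(once != flat), 1L)
})

test_that("max normalization scales to [0, 1] and is idempotent", {
  expect_equal(as.vector(maxNormalize(matrix(c(1, 2, 4), 1))),
    c(0.25, 0.5, 1.0))
  z <- matrix(0, 2, 2)
  expect_equal(maxNormalize(z), z)
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(runif(36, 0, 10), 6)
    n <- maxNormalize(m)
    expect_equal(max(n), 1)
    expect_true(min(n) >= 0)
    expect_equal(maxNormalize(n), n)
    o <- order(m)
    expect_true(all(diff(n[o]) >= -1e-12))
  }
})

test_that("preprocessCube composes TIC, hotspot and max-norm in order", {
  cube <- randomCube(6, 6, 1, seed = 10)
  out <- preprocessCube(cube)
  byhand <- ticNormalize(cube)
  ch <- truncateHotspots(intensityArray(byhand)[, , 1], 0.99)
  ch <- maxNormalize(ch)
  expect_equal(intensityArray(out)[, , 1], ch)

  # all steps off -> identity
  idcfg <- preprocessConfig(do_tic = FALSE, do_hotspot = FALSE, do_max_norm = FALSE)
  expect_equal(intensityArray(preprocessCube(cube, idcfg)), intensityArray(cube))
})

test_that("preprocessed channels have max 0 or 1 and values in [0, 1]", {
  cube <- randomCube(10, 8, 15, seed = 12)
  out <- preprocessCube(cube)
  mx <- apply(intensityArray(out), 3, max)
  expect_true(all(mx %in% c(0, 1)))
  expect_true(all(intensityArray(out) >= 0 & intensityArray(out) <= 1))
  # scale factors recorded for downstream ratio computations
  expect_length(cubeMeta(out)$channel_scale, 15)
})

test_that("occupancy filter drops sparse channels", {
  arr <- array(0, c(10, 10, 2))
  arr[, , 1] <- runif(100)
  arr[1, 1, 2] <- 1  # 1% occupancy
  cube <- MSIDataCube(arr, mz = c(100, 200))
  out <- preprocessCube(cube, preprocessConfig(occupancy_min = 0.05))
  expect_equal(dim(out)[3], 1L)
  expect_equal(mzAxis(out), 100)
  expect_equal(cubeMeta(out)$dropped_channels, 2L)
})
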