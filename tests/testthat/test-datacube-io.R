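test_that("cube construction validates invariants", {
  expect_s4_class(randomCube(), "MSIDataCube")
  expect_error(MSIDataCube(matrix(1, 2, 2), mz = 1), "3-D")
  expect_error(MSIDataCube(array(1, c(2, 2, 3)), mz = c(1, 2)), "mzAxis")
  expect_error(MSIDataCube(array(1, c(2, 2, 2)), mz = c(2, 1)), "increasing")
  expect_error(MSIDataCube(array(-1, c(2, 2, 1)), mz = 1), ">= 0")
})

test_that("mask-false pixels are forced to zero intensity", {
  mask <- matrix(TRUE, 4, 4); mask[1, ] <- FALSE
  cube <- MSIDataCube(array(1, c(4, 4, 2)), mz = c(100, 200), mask = mask)
  expect_true(all(intensityArray(cube)[1, , ] == 0))
  expect_true(all(intensityArray(cube)[2:4, , ] == 1))
})

test_that("rds matrix container round-trips bitwise", {
  cube <- randomCube(8, 8, 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  writeMSICube(cube, path)
  back <- readMSICube(path)
  expect_identical(intensityArray(back), intensityArray(cube))
  expect_identical(mzAxis(back), mzAxis(cube))
  expect_identical(pixelMask(back), pixelMask(cube))
})

test_that("a 2x2x3 cube with known values reloads identically", {
  vals <- array(c(0, 0.5, 1, 2, 3.5, 4, 0.25, 0.125, 8, 9, 10, 11), c(2, 2, 3))
  cube <- MSIDataCube(vals, mz = c(100, 200, 300))
  path <- withr::local_tempfile(fileext = ".rds")
  writeMSICube(cube, path)
  back <- readMSICube(path)
  expect_identical(intensityArray(back), vals)
  expect_true(all(pixelMask(back)))
})

test_that("1x1x1 degenerate cube round-trips", {
  cube <- MSIDataCube(array(0.7, c(1, 1, 1)), mz = 500)
  path <- withr::local_tempfile(fileext = ".rds")
  writeMSICube(cube, path)
  expect_equal(intensityArray(readMSICube(path))[1, 1, 1], 0.7)
})

test_that("getIonImage returns an independent slice with the right mz", {
  cube <- randomCube(6, 5, 4, seed = 2)
  for (k in c(1L, 4L)) {
    img <- getIonImage(cube, k)
    expect_equal(ionPixels(img), intensityArray(cube)[, , k])
    expect_equal(ionMz(img), mzAxis(cube)[k])
  }
  img <- getIonImage(cube, 2)
  before <- intensityArray(cube)[, , 2]
  img@pixels[1, 1] <- 999
  expect_equal(intensityArray(cube)[, , 2], before)
  expect_error(getIonImage(cube, 0), "out of range")
  expect_error(getIonImage(cube, 5), "out of range")
})

test_that("missing input path raises a clean I/O error", {
  expect_error(readMSICube("/nonexistent/file.rds"), "no such file")
})

test_that("imzML continuous mode round-trips within float precision", {
  mask <- matrix(TRUE, 5, 4); mask[2, 3] <- FALSE
  cube <- randomCube(5, 4, 6, seed = 9, mask = mask)
  path <- withr::local_tempfile(fileext = ".imzML")
  writeMSICube(cube, path, format = "imzml", mode = "continuous")
  expect_true(file.exists(sub("\\.imzML$", ".ibd", path)))
  back <- readMSICube(path)
  expect_equal(intensityArray(back), intensityArray(cube), tolerance = 1e-12)
  expect_equal(mzAxis(back), mzAxis(cube))
  expect_identical(pixelMask(back), mask)
})

test_that("imzML processed mode round-trips sparse spectra", {
  set.seed(5)
  arr <- array(0, c(4, 4, 5))
  arr[sample(80, 30)] <- runif(30)
  cube <- MSIDataCube(arr, mz = c(100, 150, 200, 250, 300))
  path <- withr::local_tempfile(fileext = ".imzML")
  writeMSICube(cube, path, format = "imzml", mode = "processed")
  back <- readMSICube(path, ppm = 10)
  # well-separated m/z values: binning recovers the original axis exactly
  expect_equal(mzAxis(back), mzAxis(cube), tolerance = 1e-9)
  expect_equal(intensityArray(back), intensityArray(cube), tolerance = 1e-12)
})

test_that("processed-mode peaks within 10 ppm merge into one channel", {
  # two pixels with peaks at 100.000 and 100.0005 Th: the gap (5 ppm) lies
  # inside the 10 ppm window, so a single merged channel must result
  arr <- array(0, c(2, 1, 2))
  arr[1, 1, 1] <- 3; arr[2, 1, 2] <- 7
  cube <- MSIDataCube(arr, mz = c(100.000, 100.0005))
  path <- withr::local_tempfile(fileext = ".imzML")
  writeMSICube(cube, path, format = "imzml", mode = "processed")
  back <- readMSICube(path, ppm = 10)
  expect_equal(dim(back)[3], 1L)
  expect_equal(mzAxis(back), mean(c(100.000, 100.0005)), tolerance = 1e-9)
  expect_equal(intensityArray(back)[1, 1, 1], 3)
  expect_equal(intensityArray(back)[2, 1, 1], 7)
  # at 1 ppm tolerance the peaks stay separate
  back2 <- readMSICube(path, ppm = 1)
  expect_equal(dim(back2)[3], 2L)
})

test_that("pyimzml reads imzML files written by the package", {
  cube <- randomCube(3, 3, 4, seed = 11)
  path <- withr::local_tempfile(fileext = ".imzML")
  writeMSICube(cube, path, format = "imzml", mode = "continuous")
  script <- sprintf(
    "from pyimzml.ImzMLParser import ImzMLParser
p = ImzMLParser('%s')
import numpy as np
mz, ints = p.getspectrum(0)
print(len(p.coordinates), len(mz), float(np.sum(ints)))", path)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = FALSE)
  vals <- strsplit(out[length(out)], " ")[[1]]
  expect_equal(as.integer(vals[1]), 9L)          # 3x3 pixels
  expect_equal(as.integer(vals[2]), 4L)          # 4 m/z bins
  expect_equal(as.numeric(vals[3]), sum(intensityArray(cube)[1, 1, ]),
    tolerance = 1e-6)
})

test_that("ion images slice equals array slice for random cubes", {
  for (seed in 1:3) {
    cube <- randomCube(7, 6, 5, seed = seed)
    for (k in seq_len(5))
      expect_identical(ionPixels(getIonImage(cube, k)),
        intensityArray(cube)[, , k])
  }
})
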