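test_that("pair mining recovers planted pairs on the default phantom", {
  ph <- generatePhantom(phantomConfig(seed = 3))
  prep <- preprocessCube(ph$noisy)
  pairs <- findIsotopePairs(prep)
  rep <- phantomReport(ph$truth, pairs)
  expect_gte(rep$recall, 0.9)
  expect_gte(rep$precision, 0.9)
  # deterministic output order: ascending monoisotopic m/z
  expect_true(all(diff(pairs$mono_mz) > 0))
  # diagnostics within contract ranges
  expect_true(all(pairs$corr >= 0.6))
  expect_true(all(pairs$ratio > 0 & pairs$ratio <= 1))
  expect_true(all(abs(pairs$delta_mz - 1.003355) <=
    10e-6 * pairs$mono_mz))
})

test_that("degenerate cubes yield empty pair lists", {
  one <- MSIDataCube(array(runif(64), c(8, 8, 1)), mz = 100)
  expect_equal(nrow(findIsotopePairs(one)), 0L)
})

test_that("uncorrelated channels at the right spacing are rejected", {
  set.seed(41)
  arr <- array(runif(32 * 32 * 2), c(32, 32, 2))
  cube <- MSIDataCube(arr, mz = c(400, 401.003355))
  pairs <- findIsotopePairs(cube)
  expect_equal(nrow(pairs), 0L)
  # sanity: same images duplicated do pass
  arr2 <- arr; arr2[, , 2] <- 0.5 * arr[, , 1]
  cube2 <- MSIDataCube(arr2, mz = c(400, 401.003355))
  expect_equal(nrow(findIsotopePairs(cube2)), 1L)
})

test_that("no channel appears as both mono and iso (chain breaking)", {
  # three channels in an isotopologue ladder A, A+1, A+2: accepting (A, A+1)
  # must exclude (A+1, A+2)
  set.seed(42)
  base <- matrix(runif(32 * 32), 32)
  arr <- array(0, c(32, 32, 3))
  arr[, , 1] <- base
  arr[, , 2] <- 0.4 * base
  arr[, , 3] <- 0.15 * base
  cube <- MSIDataCube(arr, mz = c(500, 501.003355, 502.00671))
  pairs <- findIsotopePairs(cube)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$mono_channel, 1L)
  expect_equal(pairs$iso_channel, 2L)
  expect_false(any(pairs$iso_channel %in% pairs$mono_channel))
})

test_that("mining is invariant under channel permutation up to re-indexing", {
  ph <- generatePhantom(phantomConfig(seed = 4, n_pairs = 6L, n_unpaired = 3L,
    n_noise_channels = 1L, shape = c(32L, 32L)))
  prep <- preprocessCube(ph$noisy)
  pairs <- findIsotopePairs(prep)
  H <- dim(prep)[3]
  set.seed(43)
  perm <- sample(H)  # channel k of the new cube = channel perm[k] of the old
  arr <- intensityArray(prep)[, , perm]
  mz <- mzAxis(prep)[perm]
  ord <- order(mz)
  meta <- cubeMeta(prep)
  meta$channel_scale <- meta$channel_scale[perm][ord]
  cube2 <- MSIDataCube(arr[, , ord], mz[ord], mask = pixelMask(prep), meta = meta)
  pairs2 <- findIsotopePairs(cube2)
  back <- match(seq_len(H), perm[ord])  # old index -> new index after sorting
  expect_equal(nrow(pairs2), nrow(pairs))
  expect_setequal(
    paste(pairs2$mono_channel, pairs2$iso_channel),
    paste(back[pairs$mono_channel], back[pairs$iso_channel])
  )
})

test_that("recall is monotone nonincreasing in the correlation threshold", {
  ph <- generatePhantom(phantomConfig(seed = 5))
  prep <- preprocessCube(ph$noisy)
  recalls <- sapply(c(0.3, 0.6, 0.9, 0.99), function(mc) {
    phantomReport(ph$truth,
      findIsotopePairs(prep, pairConfig(min_corr = mc)))$recall
  })
  expect_true(all(diff(recalls) <= 0))
})

test_that("training sets pair isotopic inputs with monoisotopic targets", {
  ph <- generatePhantom(phantomConfig(seed = 6))
  prep <- preprocessCube(ph$noisy)
  pairs <- findIsotopePairs(prep)
  tset <- buildTrainingSet(prep, pairs)
  expect_length(tset, nrow(pairs))
  d <- dim(prep)
  for (p in tset[1:3]) {
    expect_equal(dim(p$input), d[1:2])
    expect_equal(dim(p$target), d[1:2])
    expect_equal(max(p$input), 1)
    expect_equal(max(p$target), 1)
  }
  # inputs (isotopic) carry more missing pixels than targets (monoisotopic)
  zin <- mean(sapply(tset, function(p) mean(p$input == 0)))
  zout <- mean(sapply(tset, function(p) mean(p$target == 0)))
  expect_gt(zin, zout)

  expect_length(buildTrainingSet(prep, pairs[0, ]), 0L)
  bad <- pairs; bad$iso_channel[1] <- 999L
  expect_error(buildTrainingSet(prep, bad), "outside the cube")
})
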