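# Shared fixture builders; everything is generated in code at test time.

randomCube <- function(X = 8, Y = 8, H = 10, seed = 1, mask = NULL) {
  set.seed(seed)
  MSIDataCube(array(runif(X * Y * H), c(X, Y, H)),
    mz = sort(100 + runif(H) * 400), mask = mask)
}

# small phantom used by training-dependent tests
smallPhantom <- function(seed = 1, shape = c(32L, 32L), n_pairs = 8L) {
  generatePhantom(phantomConfig(
    shape = shape, n_pairs = n_pairs, n_unpaired = 4L,
    n_noise_channels = 2L, seed = seed
  ))
}

# Independent PSNR/SSIM oracle: scikit-image through the system python.
# Returns a data.frame with columns psnr, ssim, one row per pair.
metricsOracle <- function(tests, refs) {
  stopifnot(length(tests) == length(refs))
  h <- nrow(tests[[1]]); w <- ncol(tests[[1]])
  bin <- tempfile(fileext = ".f64")
  con <- file(bin, "wb")
  for (x in tests) writeBin(as.vector(x), con, size = 8)
  for (x in refs) writeBin(as.vector(x), con, size = 8)
  close(con)
  out <- tempfile(fileext = ".csv")
  script <- system.file("python", "metrics_oracle.py", package = "MSIdenoise")
  status <- system2("python", c(script, bin, h, w, length(tests), out),
    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  res <- utils::read.csv(out, header = FALSE, col.names = c("psnr", "ssim"))
  res$psnr[res$psnr == "inf"] <- Inf
  res$psnr <- as.numeric(res$psnr)
  res
}
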