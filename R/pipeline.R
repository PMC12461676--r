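#' Assemble a full pipeline configuration
#'
#' Merges the per-stage configurations into one run description. Either
#' \code{input} (a cube file readable by \code{\link{readMSICube}}) or
#' \code{phantom} (a \code{\link{phantomConfig}}) must be given; with a
#' phantom the clean truth is known and the evaluation stage runs.
#'
#' @param out_dir output directory; created if missing.
#' @param input optional path to an input cube (.rds or .imzML).
#' @param phantom optional \code{\link{phantomConfig}}.
#' @param preprocess a \code{\link{preprocessConfig}}.
#' @param pairs a \code{\link{pairConfig}}.
#' @param corruption a \code{\link{corruptionConfig}}.
#' @param preset list with \code{baseChannels}, \code{depth}, \code{train}
#'   (see \code{\link{deskPreset}}, \code{\link{paperPreset}}).
#' @param baseline a \code{\link{baselineConfig}}.
#' @param seed global seed; stage seeds are derived from it.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(out_dir, input = NULL, phantom = NULL,
                      preprocess = preprocessConfig(),
                      pairs = pairConfig(),
                      corruption = corruptionConfig(),
                      preset = deskPreset(),
                      baseline = baselineConfig(),
                      seed = 1L) {
  if (is.null(input) && is.null(phantom))
    stop("runConfig: either 'input' or 'phantom' must be provided")
  if (!is.null(input) && !file.exists(input))
    stop("runConfig: input cube not found: ", input)
  structure(
    list(
      out_dir = out_dir, input = input, phantom = phantom,
      preprocess = preprocess, pairs = pairs, corruption = corruption,
      preset = preset, baseline = baseline, seed = as.integer(seed)
    ),
    class = c("RunConfig", "list")
  )
}

writeResolvedConfig <- function(cfg, path) {
  ser <- rapply(unclass(cfg), function(x) {
    if (is.matrix(x)) as.vector(x) else x
  }, how = "replace")
  yaml::write_yaml(ser, path)
  invisible(tools::md5sum(path)[[1]])
}

#' Run the full denoising pipeline
#'
#' Stages: load or simulate the input cube; preprocess; mine isotope pairs;
#' train the denoiser on the mined pairs; denoise the whole cube; and, when a
#' phantom truth is available, run the corruption-based evaluation comparing
#' the denoiser with the Gaussian and wavelet baselines. Each stage writes
#' its artifact into \code{out_dir} so later stages can be re-run from disk;
#' a resolved-config snapshot with an md5 provenance hash accompanies the
#' outputs.
#'
#' @param config a \code{\link{runConfig}}.
#' @param verbose print stage progress (default TRUE).
#' @return invisibly, a list with the in-memory artifacts (prep cube, pair
#'   table, model, denoised cube, and eval report when computed).
#' @export
runPipeline <- function(config, verbose = TRUE) {
  cfg <- config
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- writeResolvedConfig(cfg, file.path(cfg$out_dir, "config.yaml"))
  say("[config] resolved config written (md5 %s)", hash)

  truth <- NULL
  if (!is.null(cfg$phantom)) {
    say("[simulate] generating phantom cube")
    ph <- generatePhantom(cfg$phantom)
    cube <- ph$noisy
    truth <- ph$truth
    writeMSICube(cube, file.path(cfg$out_dir, "input.rds"))
    writeMSICube(truth$clean_cube, file.path(cfg$out_dir, "clean.rds"))
  } else {
    say("[load] reading %s", cfg$input)
    cube <- readMSICube(cfg$input)
  }

  say("[preprocess] TIC/hotspot/max-normalization")
  prep <- preprocessCube(cube, cfg$preprocess)
  writeMSICube(prep, file.path(cfg$out_dir, "prep.rds"))

  say("[pairs] mining isotope pairs")
  pair_tab <- findIsotopePairs(prep, cfg$pairs)
  utils::write.csv(pair_tab, file.path(cfg$out_dir, "pairs.csv"), row.names = FALSE)
  say("[pairs] %d pairs accepted", nrow(pair_tab))
  if (!is.null(truth)) {
    rep <- phantomReport(truth, pair_tab)
    say("[pairs] recall %.3f, precision %.3f", rep$recall, rep$precision)
  }
  if (nrow(pair_tab) < 2L)
    stop("pipeline halted at stage 'pairs': fewer than 2 pairs mined")

  say("[train] training denoiser (base %d, depth %d, %d epochs)",
    cfg$preset$baseChannels, cfg$preset$depth, cfg$preset$train$epochs)
  tset <- buildTrainingSet(prep, pair_tab)
  model <- buildDenoiser(cfg$preset$baseChannels, cfg$preset$depth,
    init = if (is.null(cfg$preset$init)) "normal" else cfg$preset$init,
    seed = cfg$preset$train$seed)
  model <- trainDenoiser(model, tset, cfg$preset$train)
  utils::write.csv(
    data.frame(epoch = seq_along(model@history),
      train_loss = model@history, val_loss = model@valHistory),
    file.path(cfg$out_dir, "loss_history.csv"), row.names = FALSE
  )
  saveRDS(list(params = model@params, arch = model@arch,
    trainConfig = model@trainConfig, history = model@history,
    valHistory = model@valHistory),
    file.path(cfg$out_dir, "model.rds"))

  say("[denoise] applying the trained network to all %d channels", dim(prep)[3])
  denoised <- denoiseCube(model, prep)
  writeMSICube(denoised, file.path(cfg$out_dir, "denoised.rds"))

  report <- NULL
  if (!is.null(truth)) {
    say("[evaluate] corruption benchmark vs clean truth")
    report <- evaluatePhantomDenoising(model, truth$clean_cube,
      corruption = cfg$corruption, baseline = cfg$baseline)
    utils::write.csv(perChannel(report),
      file.path(cfg$out_dir, "eval_report.csv"), row.names = FALSE)
    utils::write.csv(aggregateReport(report),
      file.path(cfg$out_dir, "eval_aggregate.csv"), row.names = FALSE)
    if (verbose) show(report)
  }
  invisible(list(
    prep = prep, pairs = pair_tab, model = model,
    denoised = denoised, report = report, truth = truth
  ))
}

#' Corruption benchmark on a clean reference cube
#'
#' The quantitative evaluation protocol: degrade the clean cube with Poisson
#' resampling and exact-fraction missing values, re-normalize the corrupted
#' channels to [0, 1] (hotspot truncation + max normalization, the network's
#' input contract), then denoise with the trained network and both classical
#' baselines, and score every method against the clean cube with PSNR and
#' SSIM.
#'
#' @param model a trained \code{DenoiserModel}.
#' @param clean the clean reference \code{MSIDataCube} (channels in [0, 1]).
#' @param corruption a \code{\link{corruptionConfig}}.
#' @param baseline a \code{\link{baselineConfig}}.
#' @return an \code{\linkS4class{EvalReport}} with methods \code{noisy},
#'   \code{gaussian}, \code{wavelet}, \code{denoiser}.
#' @export
evaluatePhantomDenoising <- function(model, clean,
                                     corruption = corruptionConfig(),
                                     baseline = baselineConfig()) {
  # channels with no clean signal (pure-noise plants) carry no reference to
  # score against, so the benchmark runs on signal channels only
  keep <- which(apply(clean@intensities, 3, max) > 0)
  clean@intensities <- clean@intensities[, , keep, drop = FALSE]
  clean@mzAxis <- clean@mzAxis[keep]
  noisy <- corruptCube(clean, corruption)
  noisy <- preprocessCube(noisy,
    preprocessConfig(do_tic = FALSE, do_hotspot = TRUE, do_max_norm = TRUE))
  evaluateMethods(clean, list(
    noisy = noisy,
    gaussian = baselineDenoiseCube(noisy, "gaussian", baseline),
    wavelet = baselineDenoiseCube(noisy, "wavelet", baseline),
    denoiser = denoiseCube(model, noisy)
  ))
}

#' Self-contained corruption benchmark across phantom seeds
#'
#' For each seed: generate the default phantom, preprocess, mine pairs,
#' train the desk-preset denoiser on them, then run
#' \code{\link{evaluatePhantomDenoising}} and record pair-mining
#' recall/precision. Seed-averaged per-method means of PSNR and SSIM
#' summarize the comparison.
#'
#' @param seeds integer vector of phantom/training seeds (one run each).
#' @param epochs desk-preset training epochs (default 200).
#' @param shape phantom size in pixels (default 32 x 32).
#' @param verbose print per-seed progress.
#' @return list with \code{per_seed} (list of aggregate data.frames),
#'   \code{summary} (data.frame method, mean_psnr, mean_ssim averaged over
#'   seeds), \code{recall}, \code{precision} (per-seed vectors), and
#'   \code{n_channels} scored per seed.
#' @export
runDenoisingBenchmark <- function(seeds = 1:3, epochs = 200L,
                                  shape = c(32L, 32L), verbose = TRUE) {
  per_seed <- list()
  recall <- precision <- n_channels <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    seed <- seeds[i]
    ph <- generatePhantom(phantomConfig(seed = seed, shape = shape))
    prep <- preprocessCube(ph$noisy)
    pairs <- findIsotopePairs(prep)
    repmine <- phantomReport(ph$truth, pairs)
    recall[i] <- repmine$recall
    precision[i] <- repmine$precision
    pre <- deskPreset(epochs = epochs, seed = seed)
    model <- buildDenoiser(pre$baseChannels, pre$depth, init = pre$init,
      seed = seed)
    model <- trainDenoiser(model, buildTrainingSet(prep, pairs), pre$train)
    evrep <- evaluatePhantomDenoising(model, ph$truth$clean_cube,
      corruption = corruptionConfig(seed = seed + 1000L))
    agg <- aggregateReport(evrep)
    n_channels[i] <- sum(perChannel(evrep)$method == agg$method[1])
    per_seed[[i]] <- agg
    if (verbose)
      message(sprintf(
        "seed %d: recall %.2f, denoiser %.2f dB / %.3f vs gaussian %.2f dB / %.3f",
        seed, recall[i],
        agg$mean_psnr[agg$method == "denoiser"], agg$mean_ssim[agg$method == "denoiser"],
        agg$mean_psnr[agg$method == "gaussian"], agg$mean_ssim[agg$method == "gaussian"]))
  }
  comb <- do.call(rbind, per_seed)
  summary <- do.call(rbind, lapply(unique(comb$method), function(m) {
    data.frame(method = m,
      mean_psnr = mean(comb$mean_psnr[comb$method == m]),
      mean_ssim = mean(comb$mean_ssim[comb$method == m]))
  }))
  list(per_seed = per_seed, summary = summary, recall = recall,
    precision = precision, n_channels = n_channels)
}
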