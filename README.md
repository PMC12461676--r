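# MSIdenoise

Self-supervised denoising of mass spectrometry imaging (MSI) datacubes,
for analysts who have an imzML (or matrix) cube and no noise-free reference
to train against.

An MSI experiment yields a datacube *M* of dimension *X × Y × H* — one
intensity image per m/z bin. Noise-free MSI data cannot be acquired, so
supervised denoisers have no ground truth. This package builds the training
set from chemistry instead: for most molecules the +1 isotopologue (one
¹³C, +1.003355 Th) is detected next to the monoisotopic ion and should
share its spatial distribution exactly, but in practice arrives with more
missing values and outliers. Each mined pair
(*I*<sup>iso</sup>, *I*<sup>monoiso</sup>) becomes a (noisy input, pseudo
ground truth) training example for a U-Net-style convolutional
encoder–decoder *f*(·|θ), trained by minimizing the mean absolute error

&nbsp;&nbsp;&nbsp;&nbsp;*L*<sub>rec</sub> = (1/*N*) Σ<sub>i</sub> | *I*<sub>i</sub><sup>monoiso</sup> − *f*(*I*<sub>i</sub><sup>iso</sup> | θ) |,

after which every channel of the cube is passed through the trained network
to give *M*<sup>denoised</sup>.

The package also ships the surrounding machinery: imzML and RDS-container
I/O; TIC normalization, hotspot truncation and per-ion [0, 1]
normalization; a synthetic phantom generator with planted isotope pairs and
known clean truth; the Poisson + 20%-missing corruption protocol used for
quantitative evaluation; PSNR/SSIM scoring; and Gaussian-filter and
wavelet-shrinkage baselines.

## Worked example

```r
library(MSIdenoise)

ph   <- generatePhantom(phantomConfig(seed = 1))   # synthetic cube + truth
ph$noisy
#> MSIDataCube: 48 x 48 pixels, 55 m/z channels (306.0991 - 529.1820 Th)
#>   acquired pixels: 2304 / 2304; intensity range [0, 1.829]

prep  <- preprocessCube(ph$noisy)                  # TIC -> hotspot -> [0,1]
pairs <- findIsotopePairs(prep)                    # mine isotope pairs
head(pairs[, c("mono_mz", "iso_mz", "delta_mz", "corr", "ratio")], 4)
#>   mono_mz iso_mz delta_mz   corr  ratio
#> 1   312.2  313.2    1.003 0.8613 0.2642
#> 2   326.8  327.8    1.003 0.7664 0.2708
#> 3   351.6  352.6    1.003 0.8742 0.2534
#> 4   371.2  372.2    1.003 0.8114 0.2671

phantomReport(ph$truth, pairs)[c("recall", "precision")]
#> $recall    [1] 0.95
#> $precision [1] 1
```

Each mined pair matches the ¹³C spacing to 10 ppm, correlates spatially
(`corr`), and has an isotopic/monoisotopic abundance ratio (~0.26–0.27
here) below 1, as isotopologues must. Training and whole-cube inference:

```r
pre   <- deskPreset(epochs = 200, seed = 1)        # CPU-scale preset
model <- buildDenoiser(pre$baseChannels, pre$depth, init = pre$init, seed = 1)
model <- trainDenoiser(model, buildTrainingSet(prep, pairs), pre$train)
denoised <- denoiseCube(model, prep)               # all 55 channels
```

On the corruption benchmark (Poisson resampling with the pixel value as the
mean, plus exactly 20% of pixels zeroed; output scored against the phantom's
clean truth), a three-seed run prints:

```r
bench <- runDenoisingBenchmark(seeds = 1:3, epochs = 200)
bench$summary
#>     method mean_psnr mean_ssim
#>      noisy    13.221    0.2672
#>   gaussian    14.199    0.3038
#>    wavelet    13.698    0.2564
#>   denoiser    14.486    0.3197
```

The trained denoiser beats the corrupted input and both classical baselines
on both metrics — the qualitative ordering the method claims. (Absolute
values at this desk scale are far below full-scale results on real data and
are not comparable.)

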