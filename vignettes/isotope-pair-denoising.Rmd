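---
title: "Denoising MSI datacubes with isotope-pair pseudo ground truth"
author: "MSIdenoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising MSI datacubes with isotope-pair pseudo ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MSIdenoise)
```

## The problem

Mass spectrometry imaging (MSI) produces a datacube `M` of dimension
X x Y x H: one intensity image per m/z bin, thousands of bins per tissue
section. Acquisition noise — dropped pixels, anomalous intensities,
counting noise in the analyzer — degrades every channel, and unlike optical
imaging there is no way to acquire a noise-free reference of the same
section. Supervised denoising therefore has no ground truth to train
against.

The package exploits a chemical redundancy instead. For most detected
molecules the +1 isotopologue (one ^13^C substitution, +1.003355 Th) is
detected alongside the monoisotopic ion. In theory the two share an
identical spatial distribution; in practice the isotopic image is a
degraded copy — lower abundance, more missing values, more outliers. The
pair is therefore a ready-made training example: the isotopic image is the
noisy input, the monoisotopic image the *pseudo ground truth*. A
convolutional encoder-decoder trained on all such pairs learns a denoising
map that is then applied to **every** channel of the cube.

## Pipeline

1. **Preprocessing** (`preprocessCube`): per-pixel TIC normalization
   (divide each spectrum by its summed intensity), then per-ion hotspot
   truncation (values strictly above 99% of the channel maximum are clipped
   to that threshold), then per-ion max normalization to [0, 1]. The order
   is fixed so the [0, 1] guarantee — required by the network and the
   metrics — is final. Note the truncation rule, taken literally, is not
   idempotent: re-applying it lowers the clipped ceiling from `0.99*max` to
   `0.99^2*max`, because the clip itself redefines the maximum. The package
   applies it exactly once.
2. **Pair mining** (`findIsotopePairs`): candidate channel pairs whose m/z
   gap matches 1.003355 Th within 10 ppm of the monoisotopic m/z are
   accepted when (a) Pearson correlation over jointly nonzero mask-true
   pixels is at least 0.6 and computed from at least 10 such pixels, (b)
   the pre-normalization mean-intensity ratio iso/mono is at most 1 (an
   isotopologue cannot out-weigh its parent), and (c) both channels have at
   least 5% nonzero pixels. One best partner per monoisotopic channel
   (highest correlation, ties by gap accuracy), and accepted pairs are
   chain-broken so no channel plays both roles — an isotopologue ladder
   A, A+1, A+2 yields one pair, not two. Zeros are treated as missing, not
   as signal, hence the joint-support restriction.
3. **Training** (`trainDenoiser`): the mined pairs
   {input = isotopic image, target = monoisotopic image} are fed to a
   U-Net-style network and the mean absolute error
   `L_rec = (1/N) * sum_i mean(|target_i - f(input_i)|)` is minimized with
   Adam (learning rate 0.005, default momenta). A 10% validation split
   selects the returned checkpoint; the full loss history is kept.
4. **Inference** (`denoiseCube`): all H channels pass through the trained
   network; outputs are clipped to nonnegative values, mask-false pixels
   forced to zero, odd-sized images reflect-padded to a multiple of
   `2^depth` and cropped back.

## The network

Per encoder level: two 3x3 zero-padded convolutions with ReLU, then 2x2 max
pooling, channel width doubling per level; a two-convolution bottleneck;
a mirrored decoder using bilinear 2x upsampling, copy-and-concatenate skip
connections, and two convolutions per level; a final linear 1x1
convolution. The full-scale preset (`paperPreset()`) uses 64 base channels
and depth 4 (64 -> 1024 channels at the bottleneck) with flat N(0, 0.02)
weight initialization and 20000 epochs — sized for GPU training. All
desk-scale work in this package uses `deskPreset()`: 16 base channels,
depth 3, a few hundred epochs, and **He (fan-in-scaled) initialization**.
The flat 0.02-standard-deviation initializer is harmless at width 64 but at
desk widths it regularly produces networks whose ReLU activations die
before the MAE loss ever leaves the constant-zero plateau (the MAE-optimal
constant is the target median, which is 0 for sparse ion images); fan-in
scaling removes that failure mode without touching the full-scale preset.

Convolutions are computed as im2col gathers (a small C++ kernel) followed
by BLAS matrix products; the backward pass uses the transposed-convolution
identity rather than a scatter, so training runs at usable speed on one CPU
core. Whole ion images are the batch elements (batch size 256 by default,
i.e. full-batch at desk scale), matching a training set whose examples are
a few hundred images, not patches.

## Synthetic phantoms: what they emulate

Real MSI data with known truth does not exist, so `generatePhantom` builds
cubes where it does:

* organ-like regions: thresholded smooth Gaussian random fields;
* each clean ion image: a weighted sum of 1-3 region masks times a
  log-smooth intensity profile (`exp(2.2 * (field - 0.5))`, about one order
  of magnitude of in-tissue dynamic range, as real ion images show),
  max-normalized;
* monoisotopic channels: clean image times multiplicative lognormal noise
  (sdlog 0.2) with 5% of the support zeroed;
* isotopic channels: 0.3 x the same clean image, independent lognormal
  noise, 20% of the support zeroed (the extra 15% is the pairing signal the
  miner and the denoiser both rely on), and 2% of support pixels replaced
  by anomalous-expression spikes at 2-4x the pixel's true value. Spikes
  scale with the pixel rather than the channel maximum: channel-max-scaled
  spikes at 2% density would mathematically cap the joint-support Pearson
  correlation near the mining threshold for any [0, 1] image, which
  contradicts what such pairs look like in practice (strongly correlated
  with sparse point defects);
* m/z axis: molecules sit ~6.5 Th apart with the isotopologue at
  +1.003355 Th, so the only pair-spacing gaps in the axis are the planted
  ones; plus unpaired singleton ions and sparse pure-noise channels as
  distractors.

Everything derives from one seed through per-channel substreams, so adding
channels does not perturb earlier ones and every cube is bit-reproducible.

What the phantom does **not** emulate: spectral peak shape, isotope fine
structure, mass-accuracy drift, chemical background, spatially correlated
instrument artifacts. Passing the phantom benchmark therefore shows the
pipeline's machinery is sound at desk scale, not that the learned model
transfers to any particular instrument's noise.

## Corruption model and evaluation

The quantitative benchmark (`evaluatePhantomDenoising`) follows the
standard recipe for methods without ground truth: corrupt reference images,
denoise, score against the reference.

* **Poisson resampling** (`poissonCorrupt`): each pixel value v is replaced
  by `Poisson(S*v)/S`. The default S = 1 takes the [0, 1]-normalized pixel
  value itself as the Poisson mean — the literal protocol — which is very
  destructive (draws are small integers). S is exposed because corrupting
  pre-normalization counts (S in the hundreds) is the physically natural
  reading; the benchmark uses the literal S = 1.
* **Missing values** (`missingCorrupt`): exactly `floor(0.20 * n)` distinct
  mask-true pixels are zeroed, sampling without replacement — an exact
  count, not a Bernoulli rate.

Corruption is applied to the phantom's clean cube (in real data it enters
at acquisition, before preprocessing), the corrupted cube is re-normalized
to [0, 1] by the package's standard hotspot + max-normalization — the input
contract every denoiser in the comparison shares — and each method's output
is scored against the clean truth with PSNR and SSIM at data range 1.
Channels whose clean image is identically zero (pure-noise distractors)
carry no reference to score and are excluded. PSNR is
`10*log10(1/MSE)` over mask-true pixels with an infinity sentinel at
MSE = 0. SSIM follows the Wang et al. convention — 11x11 Gaussian window
(sigma 1.5), K1 = 0.01, K2 = 0.03, population covariance — computed by
Gaussian filtering with reflective boundaries, discarding a 5-pixel border,
and averaging over mask-true pixels; the implementation agrees with
scikit-image's `structural_similarity` to better than 1e-6.

The classical comparators are Gaussian filtering (sigma 1 px, reflective
boundary) and wavelet shrinkage (orthogonal Daubechies-4, periodized
2-D transform, 3 levels, soft thresholding at the universal threshold
`sigma_hat * sqrt(2 log n)` with `sigma_hat` the MAD/0.6745 estimate from
the finest diagonal subband). Neither is parameterized in the literature
this package follows, so both use these conventional defaults and are
exposed in `baselineConfig`.

## Desk-scale benchmark

The test suite and `scripts/acceptance.R` run the whole pipeline on 32 x 32
phantoms with 20 planted pairs, desk-preset training capped at 200 epochs,
three seeds — sizes chosen so a complete three-seed benchmark fits in a few
minutes on one CPU core. At these settings pair mining recovers planted
pairs with recall and precision at or above 0.9, and the seed-averaged mean
PSNR and SSIM of the trained denoiser exceed the corrupted input and both
classical baselines — the qualitative method ordering the approach claims,
at desk scale. Absolute values are far below what full-scale training on
real data reports; they are not comparable and not the point of the
benchmark.

```{r, eval = FALSE}
# the complete desk-scale experiment (about 2 minutes per seed)
bench <- runDenoisingBenchmark(seeds = 1:3, epochs = 200)
bench$summary
```

## Numerical choices and degenerate inputs

* Zeros encode missing values everywhere; mask-false pixels are zero by
  construction and excluded from every statistic.
* All-zero images pass through TIC, hotspot truncation and max
  normalization unchanged; zero-TIC pixels stay zero.
* Pairs with fewer than 10 jointly nonzero pixels are rejected outright —
  a correlation on fewer points is noise.
* Correlation ties during pair mining break on gap accuracy
  (`|delta_mz - 1.003355|`); chain-breaking processes monoisotopic
  channels in ascending m/z.
* Max-pool gradients route to the first maximum in a fixed scan order, so
  training is bit-reproducible; all stochastic steps (init, splits,
  shuffles, corruption substreams) derive from explicit seeds.
* Training aborts with a diagnostic on a non-finite loss; fewer than two
  pairs is an error, and with fewer than 10 pairs the validation split is
  empty and checkpointing falls back to the training loss.
* Processed-mode imzML peaks are binned by greedy merge within 10 ppm of a
  running bin center; that tolerance is a stand-in (the upstream peak
  alignment this package would sit behind is instrument software), exposed
  as a parameter.

## Known limitations

* The pair miner is a transparent heuristic (m/z gap + correlation +
  abundance ratio). It does not model isotope-pattern intensities, adducts,
  or isobaric interference; on real complex data a dedicated annotation
  tool can stand in front of `buildTrainingSet`.
* Only +1 isotopologue pairs are mined; +2 (common for S/Cl/Br-containing
  species) are not.
* The desk preset's network is orders of magnitude smaller than the
  full-scale architecture; its outputs demonstrate the training signal
  exists, not publication-grade denoising.
* SSIM windows straddling mask-false pixels use the full window values;
  masking applies to the aggregation only.
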