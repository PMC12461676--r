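Package: MSIdenoise
Title: Self-Supervised Denoising of Mass Spectrometry Imaging Data via
    Isotope-Pair Pseudo Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for denoising mass spectrometry imaging (MSI) datacubes
    without experimental ground truth. Monoisotopic/isotopic ion-image pairs
    are mined from the m/z axis and used as (noisy input, pseudo ground truth)
    training data for a convolutional encoder-decoder denoiser trained with a
    mean absolute error objective. The package also provides imzML and matrix
    container input/output, TIC normalization and hotspot truncation,
    a synthetic phantom generator with planted isotope pairs, a Poisson plus
    missing-value corruption simulator, PSNR/SSIM evaluation, and Gaussian
    filtering and wavelet shrinkage baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
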