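Package: lpfsc
Title: Photoacoustic Signal Denoising by Low-Pass Filtering and Sparse Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Denoising of photoacoustic (PA) radio-frequency signals by
    simultaneous low-pass filtering and sparse coding (LPFSC): the PA
    signal is modelled as the sum of a low-frequency component and a
    sparse/sparse-derivative component, and the sparse part is recovered
    by minimising a convex objective combining a zero-phase recursive
    high-pass data term with l1 and total-variation penalties, solved by
    consensus ADMM with exact proximal steps. Includes baseline denoisers
    (frame averaging, Symlet-6 wavelet shrinkage with SURE thresholds),
    an in-silico acquisition simulator for circular, linear and phased
    arrays, delay-and-sum image reconstruction, signal and image quality
    metrics (PSNR, global SSIM, CNR, FWHM), and reproducible benchmark
    drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
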