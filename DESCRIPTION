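Package: datunet
Title: Accelerated Dopamine-Transporter SPECT with Compact U-Net Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation pipeline for deep-learning acceleration
    of 123I-ioflupane (DaT) SPECT. Generates synthetic paired short (1-cycle)
    and long (5-cycle) striatal acquisitions with Poisson counting noise and
    known per-hemisphere uptake patterns, preprocesses them into training
    samples (max-count slice selection, central cropping, per-case
    normalisation), trains a family of compact U-Nets (depths 1-5) and
    classical Gaussian/bilateral filter baselines to translate 1-cycle images
    into virtual 5-cycle images, and evaluates the results with per-slice
    PSNR/SSIM, Friedman and Dunn-Holm statistics, quadratic weighted kappa
    against a gold standard, and intra-/inter-rater intraclass correlation
    coefficients via simulated readers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
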