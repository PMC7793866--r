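Package: fcstools
Title: Fluorescence Correlation Spectroscopy and FRAP Analysis of
    Diffusing Protein Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of live-cell protein dynamics measured by
    fluorescence correlation spectroscopy (FCS) and fluorescence
    recovery after photobleaching (FRAP). Implements multi-tau
    autocorrelation of photon-count traces, confocal-volume calibration
    against a reference dye, nonlinear fitting of one-component
    (3D) and two-component (3D + 2D) free-diffusion autocorrelation
    models with AIC-based model selection, bleach-corrected FRAP
    normalization and anomalous-diffusion recovery fitting, and the
    supporting image quantifications (membrane/total intensity ratio,
    Pearson colocalization with Costes auto-thresholding). A synthetic
    data layer provides analytic curves with controlled noise, a
    Brownian-dynamics photon-trace simulator with mixed cytosolic (3D)
    and membrane (2D) pools, FRAP time series with acquisition
    photobleaching, and two-channel synthetic cell images, all with
    known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble
LinkingTo:
    Rcpp
Suggests:
    patchwork,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
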