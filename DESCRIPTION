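Package: vlpmix
Title: Gaussian Mixture Morphometry of Virus-Like Particles Imaged by
    Atomic Force Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies virus-like particle (VLP) morphology from atomic
    force microscopy (AFM) topographs and resolves particle
    sub-populations with univariate Gaussian mixture models fitted by
    Expectation-Maximization. Provides an AFM-like image simulator with
    known ground truth, an edge-based particle segmentation and
    measurement chain with pixel-to-nanometre calibration, mixture
    quantile-quantile diagnostics with a linearity regression, sequential
    selection of the number of mixture components, Student-t confidence
    intervals for component means, and Pearson chi-squared comparison of
    modeled populations across aging conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jpeg,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
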