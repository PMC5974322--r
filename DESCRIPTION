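Package: boutonscope
Title: Wide-Field Spinning-Disk Calcium Imaging Analysis of Axonal Boutons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for wide-field spinning-disk confocal calcium
    imaging of thalamocortical axonal boutons: rigid registration, spatial
    filtering and temporal resampling of movie stacks, a simplified
    constrained nonnegative matrix factorization for ROI extraction with
    spike-event inference, percentile-baseline dF/F, robust-regression
    neuropil decontamination, a gamma pixel-noise model with noise-injection
    degradation studies, seed-based pixel-wise correlation mapping,
    multi-plane ROI overlap analysis, point-spread-function FWHM metrics and
    the spinning-disk optics arithmetic. A synthetic-movie generator with
    full ground truth makes every stage testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    MASS,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
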