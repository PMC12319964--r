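Package: ncsf
Title: Voxelwise Neural Contrast Sensitivity Function Encoding Models for fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward modeling and coarse-to-fine fitting of neural contrast
    sensitivity functions (nCSF) from fMRI responses to gratings varying in
    spatial frequency and contrast. Combines an asymmetric log-parabolic
    contrast sensitivity function with a Naka-Rushton contrast response
    function, predicts BOLD time series by convolution with a two-gamma
    hemodynamic response function, and estimates voxelwise parameters by grid
    search followed by bounded local optimization of the residual sum of
    squares. Includes the block-design stimulus protocol generator, minimal
    time-series preprocessing (DCT detrending, percent signal change),
    NIfTI/GIFTI/delimited-text readers and writers, and a seeded
    simulation-based parameter-recovery validation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
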