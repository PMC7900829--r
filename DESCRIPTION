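Package: veindyn
Title: Quantification of Superficial Vein Dynamics from Near-Infrared Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring superficial vein diameter and its response to
    thermal stimulation from near-infrared (NIR) reflectance image sequences.
    Provides a synthetic scene generator with known vessel geometry, motion and
    dilation; exhaustive-search block-matching stabilization; a compact seeded
    encoder-decoder convolutional network for vein segmentation; a polyline-guided
    calliper that measures vein diameter as the full width at half maximum (FWHM)
    of inverted intensity cross-sections; and the downstream vasodilation
    statistics (percent dilation, negative-exponential decay fits, diameter vs.
    skin-temperature correlation, a multiple linear-regression prediction model,
    Bland-Altman agreement and paired t-tests). All randomness is explicitly
    seeded and every stage is testable end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
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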