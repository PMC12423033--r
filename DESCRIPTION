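Package: modefc
Title: Multiscale Functional Connectivity from Multivariate Variational
    Mode Decomposition of fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes multichannel fMRI region-of-interest time series
    into narrow-band multivariate intrinsic modes with shared central
    frequencies (multivariate variational mode decomposition, solved by
    ADMM in the frequency domain), characterizes each mode by central
    frequency, bandwidth and relative energy, selects modes in the
    neurophysiological band (10-200 mHz), and derives per-mode functional
    connectivity matrices with a shuffled-mode permutation null,
    permutation t-tests under Benjamini-Hochberg false discovery rate
    control, and all-pairs cross-participant reproducibility statistics.
    Includes a synthetic fMRI cohort generator with planted band structure
    and module-level connectivity, plus a canonical double-gamma
    hemodynamic response model for block designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
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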