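Package: rsdenoise
Title: Benchmarking Noise-Regression Techniques for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates resting-state fMRI cohorts with known network signals,
    motion-coupled edge artifacts and physiological noise, applies five
    nuisance-regression techniques (motion censoring with spike regressors,
    censoring plus global-signal regression, aggressive and non-aggressive
    ICA component regression, and combined component-plus-confound
    regression), builds seed-based connectivity maps, and scores each
    technique with split-half network reproducibility, network
    identifiability, brain-edge activity, spatial smoothness and loss of
    temporal degrees of freedom, compared with nonparametric rank tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
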