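Package: omrkit
Title: Optomotor Behavior and Calcium-Imaging Trial Analysis for Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the larval zebrafish optomotor response and
    trial-structured calcium imaging across anesthesia and washout. Includes a
    closed-loop swimming simulator (bout-structured tracking with
    stimulus-conditioned turn bias and anesthesia-dependent bout rates), swim
    bout detection and turn statistics, a trial-structured fluorescence-unit
    generator with direction tuning and block-wise silencing, baseline-subtracted
    trial responses (C - C0), responsiveness and direction-selectivity indices,
    exponential and logistic recovery fits, onset/offset kinetics fits, and
    nonparametric group comparisons with median-difference effect sizes.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
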