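Package: modmedr
Title: Mediation and Moderated Mediation with Bias-Corrected Percentile
    Bootstrap Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for observed-variable mediation and two-stage moderated
    mediation analysis of survey data: psychometric scale scoring with
    Cronbach's alpha, descriptive and correlation summaries, hierarchical
    (blockwise) least-squares regression with incremental F tests, simple
    mediation with percentile and bias-corrected percentile bootstrap
    confidence intervals, conditional indirect effects at low/mean/high
    moderator levels with bootstrap tests of high-minus-low differences,
    and a synthetic-data generator that reproduces a target moment
    structure (means, standard deviations, correlations), Likert item
    batteries with target reliabilities, and path models with known
    parameters for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
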