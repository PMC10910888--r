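Package: transportr
Title: Transporting Causal Effect Estimates to External Target Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transporting an internally valid exposure-outcome
    effect estimate from an observational study population to an external
    target population. Implements a transport targeted maximum likelihood
    estimator (TMLE) of the average treatment effect (risk difference) in
    the target population, with clever-covariate fluctuation and
    efficient-influence-curve inference; a selection-diagram engine that
    classifies transportability of an effect by d-separation; crude and
    g-computation risk-difference estimators with bootstrap confidence
    intervals; positivity and covariate-overlap diagnostics; and a
    synthetic cohort generator emulating a birth-cohort-to-birth-register
    transport setting so that every stage can be exercised without access
    to sensitive individual-level data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
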