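Package: ideotypr
Title: Model-Based Rice Ideotype Design with Germplasm-Specific Trait Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based crop ideotype design. Fits and compares
    trait-parameter distributions (germplasm-specific versus literature-derived),
    estimates radiation use efficiency, canopy light extinction and specific
    leaf area from field measurements, runs a simplified daily rice
    growth-and-quality simulator under current and perturbed climate scenarios,
    ranks traits by Sobol' total-order sensitivity indices estimated on a
    radial design, compares rankings with the top-down concordance coefficient,
    and derives ideotype profiles from the top-ranked trait combinations.
    Includes stochastic generators for daily weather with Po-valley-like
    seasonality and for synthetic germplasm trait panels, so every stage runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
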