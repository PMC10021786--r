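Package: povbench
Title: Poverty Reduction Benchmarks from Health Spending Elasticities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the elasticity of the national poverty headcount ratio
    with respect to lagged per-capita government health expenditure from a
    country-year panel using a log-log country-fixed-effects regression,
    converts the elasticity into per-country poverty reduction benchmarks
    (dollars of health spending per poverty case averted) with Monte-Carlo
    uncertainty ranges, and computes the analogous cost per poverty case
    averted for social-protection-and-labor programs for comparison.
    Includes a synthetic-data generator for the full data-generating process
    so that every pipeline stage is testable without external downloads, and
    a pipeline driver that renders publication-style tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    ggplot2,
    jsonlite,
    MASS,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
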