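Package: ethnosae
Title: Small-Area Estimation of Family-Planning Indicators by Ethnic Group
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unit-level small-area-estimation (SAE) pipeline for
    family-planning indicators (contraceptive prevalence, modern
    contraceptive prevalence, unmet need, and need satisfied with modern
    methods) in ethnic-group by state domains. Combines survey microdata
    and census microdata through variable harmonization, mixed-effects
    logistic modelling with a domain random intercept, individual-level
    census prediction, benchmarking calibration of census weights to
    direct survey estimates, and parametric-bootstrap mean-squared-error
    estimation. Includes a synthetic-data generator with known truth so
    that every stage of the pipeline can be validated end to end.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
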