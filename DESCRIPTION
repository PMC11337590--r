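Package: equicatch
Title: Equity Analysis of Emergency Medical Service Catchments
Version: 0.1.0
Authors@R: person("equicatch", "maintainers", email = "maintainers@equicatch.invalid", role = c("aut", "cre"))
Description: Constructs modelled service areas for emergency medical
    resources by assigning small-area geography units to their nearest
    resource (optionally constrained within nation), aggregates population,
    area and median deprivation decile per resource, and quantifies the
    Inverse Care Law with log-linear regression, percent-change conversion
    of coefficients, Spearman rank sensitivity analysis and bivariate
    choropleth classification. Ships a seeded synthetic-geography generator
    with a configurable true effect size so every pipeline stage is
    testable without external data downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
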