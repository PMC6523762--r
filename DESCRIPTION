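Package: discurve
Title: Species Discovery Curves and Description-Rate Analysis for
    Taxonomic Checklists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing taxonomic checklists of described species:
    reading and normalising checklist tables (CSV/TSV and Darwin-Core-style
    taxon files), tabulating species richness by family across the TDWG
    world geographical scheme, computing windowed species-description rates,
    and fitting a logistic non-homogeneous renewal-process (NHRP) model to
    annual description counts. The fitted model is forward-simulated to
    predict the number of species remaining to be described, with 95%
    prediction intervals. A seeded synthetic-data generator produces
    checklists and description-year series with the statistical structure
    the analysis assumes, so the full pipeline is testable without access
    to a live taxonomic database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
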