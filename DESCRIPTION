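Package: sroikit
Title: Social Return on Investment Analysis for Health and Care Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for Social Return on Investment (SROI)
    analysis of health and care interventions: a schema-validated impact-map
    data model (stakeholders, inputs, outcomes, indicators, financial
    proxies), evidencing of outcome quantities from longitudinal
    participant-level records with proxy-respondent substitution, financial
    proxy valuation with deadweight/displacement/attribution adjustment,
    drop-off and discounting over outcome duration, SROI ratio calculation,
    and a declarative one-way sensitivity-scenario engine. Ships a fully
    worked impact map for a 12-week visual-arts program for people living
    with dementia, and a seedable synthetic three-wave cohort generator with
    known ground truth for testing the evidencing stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
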