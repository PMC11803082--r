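Package: abxdemog
Title: Age- and Sex-Disaggregated Antibiotic Prescribing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing primary-care antibiotic prescription counts
    disaggregated by month, drug, age band, sex and region, in the form
    distributed by the NHS Business Services Authority (23 age bands,
    small-number suppression of counts below five). Provides parsing and
    exclusion handling with redaction imputation, prescription rates per
    100,000 population against ONS-style mid-year denominators, a rule-based
    seasonality classifier for monthly count series, Updated Comparison
    Metric (UCM) age-sex prescribing weights in the STAR-PU tradition with
    regional ranking, WHO AWaRe Access-share target evaluation,
    influenza-season relative-rate analysis for respiratory-tract-infection
    antibiotics, a redaction-imputation sensitivity scan, and a synthetic
    prescription-data generator with retained ground truth for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
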