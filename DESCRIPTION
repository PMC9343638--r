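Package: fluorisk
Title: Groundwater Fluoride Hazard Mapping and Population Exposure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the probability that groundwater fluoride exceeds the
    WHO drinking-water guideline of 1.5 mg/L from point measurements and
    gridded environmental covariates, using a class-balanced random forest
    with recursive feature elimination (one-standard-deviation rule),
    repeated stratified cross-validation with down-sampled balanced kappa,
    sensitivity-specificity crossover cutoffs, binned-prevalence Kendall
    association statistics, hazard-map prediction over covariate grids, and
    three population-at-risk estimators (probability-weighted, cutoff, and
    hybrid). Includes a synthetic-data generator with known ground truth so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
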