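Package: pocbudget
Title: Particulate Organic Carbon Concentrations and Their Uncertainty Budget
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines particulate organic carbon (POC) concentrations from
    CHN elemental-analyser measurements of stacked-filter samples and
    quantifies their uncertainties. Fits per-run robust calibrations with
    prediction-interval mass uncertainties, applies capsule and filter blank
    corrections, estimates whole-dataset experimental uncertainty from
    duplicate samples via a percentile-based robust standard deviation,
    propagates modelled uncertainty components (volume, calibration,
    contamination) into an uncertainty budget, and computes IUPAC critical
    values and detection limits. A synthetic-cruise generator with known
    ground truth reproduces the tabular layout of an Atlantic meridional
    transect dataset so that every stage of the pipeline can be validated
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
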