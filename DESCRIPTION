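Package: isochase
Title: Isotope Dilution Kinetics from Whole-Plant 13CO2 Metabolic Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stable-isotope metabolic labeling experiments in which
    whole plants are grown under 13CO2 and then chased with ambient air.
    Implements theoretical isotope-pattern prediction for arbitrary elemental
    compositions with element-specific 13C enrichment, atom-percent enrichment
    estimation by correlation of predicted against measured isotope
    distributions, amino-acid turnover by mass isotopomer distribution
    analysis (MIDA) with first-order decay fitting, and peptide/protein
    turnover by three-component beta-binomial mixture modeling of isotope
    envelopes extracted from LC-MS data (mzXML or peak-list input). A
    synthetic-data generator reproduces the statistical structure of the
    labeling experiment so every estimator is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    mzR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
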