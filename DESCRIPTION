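Package: gemtree
Title: Survival-Tree Analysis of Gemcitabine-Pathway Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for tumor-vs-normal relative quantification of
    gemcitabine-pathway genes (hENT1, CHOP, MRP1, DCK) and discovery of
    prognostic risk classes in resected pancreatic cancer cohorts. Implements
    comparative (2^-ddCt) relative quantification with expression-level
    statistics, person-years incidence rates, a Cox proportional-hazards
    fitter with Breslow tie handling, and a RECPAM-style survival tree:
    recursive binary partitioning by Cox likelihood-ratio splits with
    permutation-based splitting-variable selection and gating, explicit
    stopping rules, and amalgamation of leaves into hazard-ratio-ranked risk
    classes. A synthetic cohort generator with planted threshold-defined
    hazard subgroups makes every stage testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    readr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
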