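Package: twincrp
Title: Genetically Sensitive Twin-Cohort Analysis of Childhood
    Victimization and C-Reactive Protein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetically sensitive cohort analyses linking
    childhood poly-victimization to C-reactive protein (CRP) in young
    adulthood. Provides a seeded synthetic same-sex twin cohort generator
    calibrated to published twin correlations and exposure distributions;
    dried-blood-spot to serum CRP conversion, acute-inflammation
    exclusions, winsorized exposure coding and tertile flags; within-pair
    correlations, maximum-likelihood ACE variance decomposition and a
    co-twin latent genetic risk score; a from-scratch linear generalized
    estimating equation (GEE) estimator with exchangeable working
    correlation and cluster-robust sandwich variance; and a pipeline
    orchestrator with a publication-style model-ladder report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
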