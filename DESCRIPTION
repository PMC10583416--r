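Package: medimr
Title: Drug-Target Mendelian Randomization with Mediation Through
    Circulating Metabolites
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) toolkit for
    drug-target analyses with a two-step mediation design: instrument
    selection for a drug-target exposure (eQTL filtering, biomarker
    significance, approximate-Bayes-factor colocalization, greedy LD
    clumping, per-variant F statistics), allele harmonization of GWAS
    summary statistics, the full univariable estimator battery (IVW,
    MR-Egger, weighted median, simple and weighted mode, Cochran's Q),
    outlier diagnostics (MR-PRESSO and radial MR), multivariable MR,
    and product-of-coefficients mediation with delta-method confidence
    intervals. Includes a seeded generator of synthetic two-sample GWAS
    summary statistics with known ground truth, and an end-to-end
    pipeline that screens a mediator panel with Bonferroni-corrected
    thresholds and reports mediated proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
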