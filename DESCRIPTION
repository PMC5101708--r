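Package: twinpk
Title: Twin-Study Heritability Analysis of Pharmacokinetic Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for repeated-dose pharmacokinetic twin
    studies. Provides non-compartmental analysis (terminal slope estimation,
    linear-up/log-down trapezoidal AUC, clearance, volume of distribution),
    maximum-likelihood twin variance-component models (ACE, ADE, AE, CE, E and a
    saturated baseline) with AIC selection, likelihood-ratio tests and bootstrap
    confidence intervals, the repeated-measures genetic component
    rGC = (Vb - Vw)/Vb with random-sibling resampling, nonparametric
    genotype-phenotype association testing (Jonckheere-Terpstra trend and
    Mann-Whitney U with exact small-sample p-values), multiple regression with
    dietary covariate scores, genotype-based zygosity verification, and a
    seeded synthetic twin-cohort generator with known variance-component,
    linkage-disequilibrium and covariate structure for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
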