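Package: statintol
Title: EMR Phenotyping and Pharmacogenetic Association Analysis of Statin Intolerance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for pharmacogenetic studies of statin
    intolerance built on longitudinal prescribing records. Classifies
    patients from electronic medical records into general statin
    intolerance (GSI) and low-dose intolerance (LDI) cases versus
    statin-tolerant controls (ST1/ST2) using prescription coverage,
    statin switching, discontinuation and creatine kinase (CK) rules;
    tests single-variant dominant-model association by covariate-adjusted
    logistic regression with backwards stepwise elimination; fits
    genotype-by-treatment interaction and genotype-stratified
    proportional-hazards models for randomized-trial data; and pools
    per-study odds ratios by inverse-variance fixed-effects
    meta-analysis. A seeded synthetic cohort generator emulates the
    prescription, laboratory, genotype and trial structure the analysis
    assumes, so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
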