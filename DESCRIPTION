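Package: ftcdlat
Title: Functional Transcranial Doppler Language Laterality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of functional transcranial Doppler (fTCD)
    language-laterality recordings in children: heart-cycle integration,
    signal normalisation, dropout imputation, artefact rejection, epoching,
    baseline correction, and computation of the laterality index (LI) with
    trial-wise standard errors, confidence-interval categorisation and
    split-half reliability. Includes scoring of the adapted Edinburgh
    Handedness Inventory and the Quantification of Hand Preference task,
    dominance-consistency coding, classification of developmental language
    disorder from normed test batteries, and twin-aware group-comparison
    statistics (linear and logistic mixed models, a Bayesian multinomial
    multilevel model, zero-one-inflated beta regression, and replicated
    Spearman correlation screens). A synthetic-cohort generator with known
    ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
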