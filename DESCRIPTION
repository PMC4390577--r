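Package: blupga
Title: Genomic Prediction with Trait-Specific Relationship Matrices (BLUP|GA)
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Whole-genome prediction of breeding values with GBLUP, RRBLUP
    and BLUP|GA, a model that blends the genomic relationship matrix G with
    a genetic-architecture matrix S built from top-effect SNPs selected in
    the training data, T = omega * S + (1 - omega) * G. Includes
    restricted-maximum-likelihood variance-component estimation for a
    single genomic random effect, the two-stage cross-validated grid
    search over the BLUP|GA hyperparameters (top%, nflank, omega),
    model-choice diagnostics (cumulative genetic-variance curves, the
    T-G distance statistic and its regression on the accuracy gain), a
    quantitative-trait simulator with gamma- or normal-distributed QTL
    effects for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
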