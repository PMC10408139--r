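Package: oxisig
Title: Cross-Species Hyperoxia Gene-Signature Scoring and Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving sex- and genotype-specific hyperoxia
    differential-expression signatures from neonatal mouse lung RNA-seq,
    projecting them onto independent human expression cohorts with the
    summed z-score method, correlating signature scores with clinical
    covariates of bronchopulmonary dysplasia, and detecting concordant or
    discordant pathway enrichment across contrasts with permutation-based
    preranked gene-set enrichment. Includes a negative-binomial factorial
    count simulator with planted effects, a synthetic reference cohort and
    clinical cohort generator, ortholog symbol translation, a 2^-ddCt
    qRT-PCR fold-change utility, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
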