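Package: reverta
Title: Treatment-Reversal and Genotype-Dependence Analysis of Aging Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for detecting transcriptome
    "rejuvenation": RPKM quantification and expression filtering of bulk
    RNA-seq count matrices, per-gene two-group contrasts with
    Benjamini-Hochberg false discovery rate control, a three-criterion
    classifier for aging-associated genes whose expression is reversed by a
    treatment, a wild-type versus tissue-specific-knockout partition of
    treatment-responsive genes into genotype-dependent and
    genotype-independent sets, and Kaplan-Meier lifespan summaries with
    log-rank comparison. Ships a negative-binomial count simulator and a
    Weibull lifespan simulator with planted ground truth so every classifier
    can be exercised end-to-end with known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
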