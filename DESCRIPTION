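Package: isomite
Title: Reproductive Isolation Barriers Versus Genetic Distance in Haplodiploid Mite Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for crossing experiments in arrhenotokous
    (haplodiploid) spider mites, where fertilization failure is visible as a
    male-biased offspring sex ratio. Computes reproductive-isolation indices
    from offspring count tables (lack of fertilization, hybrid female
    inviability, total isolation, hybrid female sterility), Kimura
    2-parameter mitochondrial distances from aligned sequences, overdispersed
    (quasibinomial) logistic regressions of barrier strength on genetic
    distance with sequential quasi-F tests and the associated
    model-simplification procedure, and analytic inversion of the fitted
    logit models to the genetic distance at which each barrier reaches a
    stated completeness (e.g. 99.0% or 99.9%). Includes a seedable
    beta-binomial simulator of the seven-population crossing design and a
    K2P sequence-pair evolver for validating the distance estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    ape,
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
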