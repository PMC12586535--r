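Package: twinase
Title: Allele-Specific Expression Screening in Discordant Monozygotic Twins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens for phenotype-associated allele-specific expression (ASE)
    of lncRNA transcripts in phenotype-discordant monozygotic twin cohorts.
    Fits binomial (or beta-binomial) logit mixed models of the alternative
    allele read proportion with and without a disease-status fixed effect and
    compares them by Bayes factors computed from Laplace / adaptive
    Gauss-Hermite marginal likelihoods, with brute-force quadrature and
    importance-sampling oracles. Includes the upstream genotype and annotation
    filtering cascade, per-individual allelic-imbalance summaries, a
    genotype-dependent co-expression screen with BH false-discovery control,
    set-overlap enrichment, and a synthetic twin-cohort generator that
    emulates the allelic-count structure the models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
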