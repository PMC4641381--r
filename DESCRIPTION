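Package: ftdconv
Title: Rare-Variant Burden, Isobaric-Tag Proteomics and Literature-Semantic
    Convergence Analysis
Version: 0.1.0
Authors@R:
    person("FTD", "Convergence Maintainers", email = "maintainers@ftdconv.example",
           role = c("aut", "cre"))
Description: A desk-scale implementation of a multi-omic convergence
    pipeline for neurodegenerative disease genetics: rare-variant gene-burden
    testing on cohort variant tables (allele collapsing, Pearson chi-squared,
    odds ratio with Woolf confidence interval), 8-plex isobaric reporter-ion
    (iTRAQ) protein quantification with a 2-standard-deviation significance
    rule, Venn-style common/unique/contra-regulation set separation,
    hypergeometric over-representation analysis with a hybrid enrichment
    score, latent semantic indexing of a gene-linked literature corpus, and
    housekeeping-normalized relative expression statistics. Seeded synthetic
    data generators emulate each input so the whole chain is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
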