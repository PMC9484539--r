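Package: cernakit
Title: Competing Endogenous RNA Network Inference from Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for joint analysis of long noncoding RNAs,
    circular RNAs, microRNAs and mRNAs from count-based RNA-seq profiles of
    paired tumor/normal cohorts. Provides expression filtering and
    median-of-ratios normalization, negative-binomial differential expression,
    nearest-template-prediction subclass and prognosis classification,
    back-splice junction origin annotation, strict-seed miRNA target site
    discovery, hypergeometric plus co-expression assembly of competing
    endogenous RNA (ceRNA) networks, co-expression-ranked gene-set enrichment,
    and Kaplan-Meier/Cox survival screening. A synthetic-cohort generator with
    planted ground truth (fold changes, sponge triplets, subclass templates,
    junction origins, prognostic hazards) supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    MASS,
    survival,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
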