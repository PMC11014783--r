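Package: chvarfilt
Title: Consensus Calling, Error Filtering and Driver Annotation for
    Clonal Hematopoiesis Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling toolkit for deep targeted sequencing of
    clonal hematopoiesis (CH). Merges per-caller somatic VCFs into consensus
    records, filters sequencing artifacts with a panel-of-normals (PoN)
    Fisher exact error model with panel-wide Bonferroni correction plus a
    suite of rule-based false-positive filters, classifies CH putative
    drivers with a curated knowledge-base rule cascade, and triages variants
    into pass, review, and fail sets. Includes VAF-binned sensitivity and
    positive-predictive-value benchmarking with Clopper-Pearson intervals,
    replicate-concordance classification, a PoN-size sweep, and a seeded
    synthetic cohort simulator so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    jsonlite,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
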