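Package: gcgerm
Title: Germline Candidate-Gene Prioritization for Early-Onset Gastric Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully tested implementation of a multi-stage germline
    variant prioritization cascade for early-onset gastric cancer exome cohorts:
    quality, consequence, population-frequency and pathogenicity-predictor
    consensus filtering; cancer-gene restriction with dominant, recessive and
    optional compound-heterozygous inheritance analyses; a cohort recurrence
    exclusion; and read-evidence/sequence-context prevalidation heuristics.
    A companion somatic module provides multi-caller consensus merging, tumor
    mutational burden classification, SBS-96 and ID-83 mutational catalogs and
    non-negative least-squares refitting of signature exposures against a
    COSMIC-style catalog, whose mismatch-repair aetiology tags inform final
    candidate scoring. A seeded synthetic-cohort generator with a ground-truth
    manifest makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    pracma,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
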