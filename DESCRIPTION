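Package: stra8pipe
Title: Integration of Replicated Promoter ChIP Peaks with Staged Expression
    at Meiotic Initiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs, as a reusable and tested pipeline, the analysis by
    which promoter-bound and transcriptionally activated target genes of the
    meiotic initiation factor STRA8 are defined from replicated ChIP-seq peak
    calls and staged preleptotene expression profiles. Provides blacklist
    filtering and summit-to-TSS peak assignment, replicate-consensus target
    calling with control subtraction, IUPAC degenerate-motif scanning and
    motif dose-response analysis for the CNCCTCAG core motif, gene-level TPM
    aggregation with expressed-gene filtering and a plumbing differential
    expression stage, bound-by-direction contingency statistics, a nine-tissue
    testis-bias classifier, a set-overlap and enrichment statistics toolbox
    computed in log space, the closed-form seminiferous-epithelium cell-census
    estimator of the STRA8-expressing preleptotene fraction of the adult
    testis, and a seeded synthetic-data generator that emulates the statistical
    structure of the real data so the whole pipeline is testable without any
    sequencing download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    limma
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
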