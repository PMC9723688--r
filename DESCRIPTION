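Package: editcheck
Title: Misassembly-Aware Verification of Candidate RNA-Editing Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls candidate RNA variant sites from read alignments and
    eliminates those explained by matching genomic DNA polymorphisms, by
    disappearance under an independent re-alignment, by full-length exact
    matches in pooled raw genomic reads, or by collapsed near-identical
    duplications revealed through cross-assembly liftover. Distinguishes
    genuine RNA editing (e.g. fungal A-to-G transitions) from artifacts of
    genome misassembly and strain differences. Includes a deterministic
    simulator of collapsed-duplication artifacts, genuine editing and
    strain SNPs with ground truth, so the whole pipeline is testable at
    desk scale, plus multi-sample orchestration and summary reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    BiocGenerics,
    S4Vectors,
    IRanges,
    Biostrings,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
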