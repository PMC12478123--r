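Package: tsacapture
Title: Capture-Based Prediction of Non-Canonical Tumor-Specific Antigens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts non-canonical tumor-specific antigens (ncTSAs) from
    reference-guided transcript assemblies of tumor RNA-seq data. Builds a
    control "capture" database from healthy-tissue transcript models,
    captures tumor transcript fragments that are absent (novel) or sparsely
    covered (differential) in the controls, translates them with
    reference-protein- or Kozak-guided reading-frame selection, generates
    candidate peptides with read-support and majority-vote SNP correction,
    filters self-peptides against a reference proteome, labels HLA binders,
    annotates endogenous retrovirus overlap, and quantifies cassette-exon
    inclusion through isoform expression fractions. Includes a deterministic
    synthetic-data generator with planted antigens for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    rlang,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    tibble,
    dplyr,
    yaml,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
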