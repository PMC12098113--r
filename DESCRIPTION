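Package: splicepitope
Title: Discovery of Splice-Derived Neoantigens from Differential Alternative Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discovering candidate neoantigens that arise from
    differential alternative-splicing events between two sample groups
    (for example old versus young blood cohorts). Parses rMATS-style
    junction-count tables for the five canonical event types (SE, A5SS,
    A3SS, MXE, RI), applies significance filtering on deltaPSI and FDR,
    reconstructs inclusion- and exclusion-form transcript isoforms
    against a reference genome and annotation, compares coding
    sequences, enumerates splice-specific 9-mer peptides by library
    subtraction, scores them against HLA class-I alleles through a
    pluggable percentile-rank predictor, aggregates cohort presentation
    statistics, and confirms candidates against observed proteomic
    peptide lists. A fully self-contained synthetic-cohort generator
    with machine-readable ground truth makes every stage testable
    without external data. Also includes event-level analytics:
    PSI-expression correlation screens, protein-domain overlap, and
    RNA-binding-protein motif density maps around event flanks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
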