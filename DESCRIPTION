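Package: phylomine
Title: Phylogeny-Driven Mining of Transporter Gene Families from
    Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for mining gene families (built around the
    plant sugar-transporter superfamilies MST, SUT and SWEET) from de novo
    transcriptome assemblies: six-frame translated homology screening with
    Karlin-Altschul E-value filtering and best-hit confirmation, iterative
    phylogeny-driven curation (redundancy removal, long-branch outlier
    detection, isoform collapsing on neighbor-joining p-distance trees),
    reference-anchored clade classification with a per-species census,
    life-cycle stage-of-strongest-expression profiling from isoform-summed
    FPKM, and motif-architecture and orthogroup association summaries.
    Includes a synthetic-transcriptome generator with a machine-readable
    truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    phangorn
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
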