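Package: grasp2r
Title: Gene-Centric Assembly and Homolog Search for Short Peptide Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reference implementation of the GRASP2 simultaneous alignment and
    assembly strategy for metagenomic short-peptide data. Reads are indexed in
    blockwise multi-string Burrows-Wheeler transforms with FM-index queries,
    maximal suffix-prefix overlaps are detected to build an SNP-aware string
    graph, cross-block containment artifacts are rectified by sequence-identical
    bubble removal and containment-gated tip trimming, and unbranched paths are
    collapsed into unitigs. Given a reference protein, seeded ungapped extension
    selects anchor unitigs, depth-first traversal spells candidate homologous
    paths, and banded Smith-Waterman with Karlin-Altschul E-values accepts
    homologous contigs onto which the original reads are recruited. Includes a
    synthetic peptide-community simulator with planted homologs and ground-truth
    labels, and recall/precision/ROC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
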