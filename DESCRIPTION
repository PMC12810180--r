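Package: cimclash
Title: Crosslink-Induced Mutation Analysis for CLASH Small RNA Target Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects small RNA-mRNA hybrid (chimeric) reads in CLASH and
    CLASH-like sequencing libraries, calls crosslinking-induced mutations
    (CIMs, i.e. reverse-transcription deletions and substitutions at the
    protein-RNA crosslink) on the mRNA arm from CIGAR/MD alignments, maps
    them into small-RNA-relative coordinates, profiles base pairing around
    CIMs, aggregates hybrids into target sites with abundance and score
    tiers, and scores functional relevance via CIM enrichment and
    rank-based/permutation fold-change statistics. Ships a synthetic CLASH
    library simulator with full ground truth so every pipeline stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
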