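Package: satarray
Title: Decomposition and Higher-Order Repeat Analysis of Satellite DNA Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting tandemly repeated satellite DNA. Segments
    multimeric cloned arrays into monomers with the Key-String Algorithm,
    groups monomers into families with global-alignment identity matrices and
    neighbor-joining trees with bootstrap support, profiles per-site sequence
    variability with sliding windows, discovers short boxes conserved across
    highly divergent families and scores their similarity to the human CENP-B
    box, annotates arrays with labeled monomers to infer higher-order repeat
    (HOR) units, and characterizes monomer junctions including box-bounded
    cut-and-paste replacements, box-mediated recombination junctions and
    overlap junctions. A seeded simulator generates satellite libraries,
    arrays and rearrangement events with known ground truth so that every
    stage can be validated by structure and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
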