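Package: phasiCascade
Title: Plant Small RNA Target Prediction, Degradome Validation, and
    Phased siRNA Cascade Inference
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the inference chain used to discover
    miRNA-triggered phased siRNA (phasiRNA) cascades on plant
    transcripts: expectation-scored small RNA target prediction with
    seed-region penalty weighting, miRNA precursor validation against
    hairpin criteria (read support, folding free energy, duplex 3'
    overhangs and bulges, MFEI), degradome (PARE) t-plot construction
    with five-level cleavage categories and site validation, 21-nt
    phasing-locus detection with a PhaseTank-style score and a
    hypergeometric register test, phasiRNA register enumeration and
    naming, secondary-trigger inference, and cascade network assembly.
    A seeded synthetic-data generator with recorded ground truth makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: SmallRNA, Transcriptomics, Alignment, GeneRegulation
RoxygenNote: 7.3.3
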