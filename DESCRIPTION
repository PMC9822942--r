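Package: phytomir
Title: Plant miRNA Target Prediction with Duplex Features and Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts plant miRNA target sites on mRNA transcripts without
    relying on canonical seed rules. Candidate sites are found by a
    miRanda-style complementarity alignment (Watson-Crick and G:U wobble
    pairing, affine gaps), each miRNA:site duplex is summarised by eleven
    features (hybridization free energy, seed match, site accessibility,
    AU content, m/e motif score and six pairing-geometry counts), and a
    13-tree random forest scores candidate interactions with a confidence
    in [0,1]. Includes matched negative-exemplar generation (non-overlapping,
    CG-dinucleotide-matched, minimum-energy windows), homology-controlled
    train/test splitting at 70% miRNA identity, precision-recall evaluation,
    five-fold cross-validated confidence-threshold selection, and a synthetic
    corpus generator with planted binding sites for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr,
    yaml
VignetteBuilder: knitr
SystemRequirements: ViennaRNA (RNAduplex and RNAplfold on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
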