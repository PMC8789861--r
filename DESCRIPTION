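Package: moffr
Title: Model-Based Prediction of CRISPR/Cas9 Off-Target Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and predicting the specificity of
    CRISPR/Cas9 genome editing. Implements the dual-target synthetic
    screen workflow (oligonucleotide library design, amplicon read
    classification, non-negative least-squares inference of cleavage
    states and off-on ratios), the decomposition of off-on ratios into
    single-mismatch effects (M1), guide-intrinsic mismatch tolerance
    (GMT) and pairwise combinatorial effects (M2/delta), a dinucleotide
    convolutional regression that predicts GMT from guide sequence, a
    multi-state kinetic model of R-loop formation, and the MOFF family
    of scores: MOFF-target for a single gRNA/off-target pair,
    MOFF-aggregate for genome-wide specificity, and MOFF-allele for
    allele-discriminating mismatched guide design. Seeded synthetic-data
    generators produce every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    Matrix,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
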