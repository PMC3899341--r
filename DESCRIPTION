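Package: hybridaln
Title: Hybrid-Seeding Short-Read Alignment in Base and Color Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: A sensitive seed-and-extend short-read aligner for base-space
    (Illumina-like) and color-space (SOLiD-like) reads against small reference
    genomes. Reads are anchored with a hybrid of maximal exact match seeds,
    non-overlapping exact-match k-mer seeds and variable-length seeds derived
    from optimal local alignments, found with an FM-index over the reference,
    and extended with affine-gap Smith-Waterman or semi-global dynamic
    programming. Paired-end alignment uses a weighted seed-pairing heuristic,
    alignment-pair ranking by weight and edit distance, and read mate rescuing
    inside the insert-size window. Includes a wgsim-style read simulator with
    recorded truth, an evaluator computing sensitivity, recall and MAPQ-ordered
    ROC curves, and a standards-compliant SAM writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
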