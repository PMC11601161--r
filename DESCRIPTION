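Package: strataln
Title: Protein Structure Alignment with Factored Structural Alphabets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns protein structures by sequence-alignment dynamic
    programming over discretized per-residue structural features. Each
    C-alpha is described by its amino acid plus local-conformation and
    Euclidean-neighbour features, condensed into letters from small
    per-feature alphabets whose Cartesian product forms a very large
    factored "mega-alphabet". Per-feature log-odds matrices are trained
    from reference alignments, local alignments are found by affine-gap
    Smith-Waterman, and alignment significance is summarized by an
    alignment-quality statistic with empirically calibrated E-values.
    Includes a synthetic-backbone simulator and a homology-benchmark
    harness (coverage-versus-error and top-hit category curves).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
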