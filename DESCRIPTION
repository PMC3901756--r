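Package: phylopi
Title: Phylogenetic Informativeness Profiling and Marker Utility Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates the phylogenetic utility of sequence markers on a
    fixed time-calibrated tree. Estimates per-site substitution rates by
    maximum likelihood (Felsenstein pruning under JC69 on an ultrametric
    tree with branch lengths in Ma), computes phylogenetic informativeness
    profiles over time in three variants (original normalized, modified,
    and per-base average-modified), classifies alignment columns as
    conserved, variable or parsimony-informative per partition, builds
    substitution-saturation tables of uncorrected p-distances against
    patristic distances, and summarizes offset lognormal and offset
    exponential fossil-calibration priors. Includes a partitioned sequence
    simulator (Yule trees, HKY with gamma site rates, fragment-level
    missing data) so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    seqinr,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
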