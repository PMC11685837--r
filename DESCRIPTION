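Package: stabmut
Title: Design, Clustering, and Greedy Accumulation of Protein-Stabilizing Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for computational protein-thermostability
    engineering. Builds single-point stabilizing-mutation libraries by
    thresholded multi-predictor consensus (FoldX/Rosetta/ABACUS-style score
    tables behind a pluggable scorer interface, plus multiple-sequence-alignment
    consensus design), computes structure-based feature vectors for validated
    stabilizing mutations (hydrogen-bond and hydrophobic-contact changes,
    a backbone-entropy flag, and C-alpha coordinates), clusters mutations for
    parallel experimental tracks, and plans greedy accumulation of mutations
    over optionally epistatic combination landscapes, with a synthetic
    landscape simulator and exhaustive oracle for benchmarking the greedy
    strategy, and binary-classification metrics for comparing stability
    predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    cluster,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
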