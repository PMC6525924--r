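Package: tritensor
Title: Disease-Associated lncRNA-miRNA Pair Prediction by Nonnegative
    Tucker Tensor Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts disease-associated lncRNA-miRNA pairs from three
    binary association networks (disease-lncRNA, disease-miRNA,
    lncRNA-miRNA). The three bipartite networks are closed into a
    tripartite network whose triangles populate a binary three-way
    association tensor; sparse interaction profiles are densified with
    similarity-weighted K-nearest-neighbor smoothing driven by MeSH-based
    disease semantic similarity, Gaussian interaction-profile kernels and
    best-match functional similarities; the smoothed tensor is completed
    with a nonnegative Tucker decomposition fitted by alternating
    multiplicative updates, and candidate pairs are ranked per disease
    from the reconstruction. Includes global/local leave-one-out and
    repeated k-fold cross-validation, recall-at-k curves, parameter
    sweeps, and a seeded generator of coupled synthetic networks with
    planted low-rank block structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
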