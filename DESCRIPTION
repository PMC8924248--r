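Package: deconvbench
Title: Benchmarking Cell-Type Deconvolution of Brain Bulk Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation-based benchmarking of partial deconvolution of bulk
    brain RNA-seq. Generates synthetic single-cell/single-nucleus count data
    with planted cell-type structure, constructs pseudo-bulk mixtures with
    known composition (both the share of cells, pCt, and the share of RNA
    reads, pRNA), builds and merges cell-type signature matrices, estimates
    composition with four partial-deconvolution solvers (non-negative least
    squares, nu-support-vector regression, a marker-offset linear-mixing
    estimator, and subject-weighted NNLS), and quantifies accuracy (Pearson r,
    normalised mean absolute error, reconstruction goodness-of-fit). Also
    quantifies how cell-type composition differences between sample groups
    confound differential expression, and how composition covariates restore
    discriminatory power.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    splines,
    pracma,
    e1071,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
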