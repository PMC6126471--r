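Package: barnyard
Title: Multiplet Frequency Estimation from Two-Species Cell-Mixing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form Poisson estimator of the multiplet frequency in
    droplet- or well-based single-cell RNA-seq from two-cell-type mixing
    ("barnyard") experiments at arbitrary mixing proportions. Given the
    observed numbers of partitions containing each cell type and both types,
    the package inverts the Poisson loading model to recover the per-type mean
    cells per droplet and the total (empty plus non-empty) droplet count, and
    evaluates the probability that a non-empty partition holds two or more
    cells. Includes a seeded Monte-Carlo droplet-loading simulator (Poisson
    and two clumped variants) for validating estimator recovery, a
    species-purity classifier that derives the three observable counts from a
    cellranger-style mixed-species gene-barcode matrix, a parametric bootstrap
    interval, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
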