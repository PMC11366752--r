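Package: celldist
Title: Condition Distances for Cell Types in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential state analysis for annotated single-cell RNA-seq
    experiments. For each cell type, the Euclidean distance between the two
    condition means in normalized expression space is estimated with a
    random-intercept linear mixed model fitted on a low-dimensional principal
    component projection, shrunk with an empirical-Bayes spike-and-slab prior,
    and tested against a Monte-Carlo sum-of-F null distribution. Includes
    Pearson-residual normalization of UMI counts, gene-level importance scores
    and differential signatures, annotation diagnostics (pairwise cell-type
    distances, multi-resolution trees, cell-number variation), and simulators
    for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    jsonlite,
    withr
Config/testthat/edition: 3
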