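Package: poisde
Title: Poisson-Model Differential Expression and Replicate Consistency for
    RNA-Seq Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression analysis for RNA-Seq read-count matrices
    under a per-lane Poisson model. Implements a likelihood-ratio method
    (within-condition homogeneity tests across technical replicates and a
    two-condition test on pooled counts) and a Bayesian method that
    generalizes the Audic-Claverie predictive distribution to any number of
    replicates, with integer acceptance intervals used both for replicate
    consistency checks and for two-sample differential-expression calls.
    Also provides the three count normalizations commonly assessed alongside
    these tests (total-count scaling to parts per million, trimmed mean of
    M-values, and median-reference quantile normalization), a gene
    categorization workflow with a presence filter and fold changes, a
    seeded Poisson count simulator for calibration and power studies, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
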