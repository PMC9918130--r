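Package: plsdaRank
Title: PLS-DA Latent-Axis Gene Ranking for Three-Group Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Candidate-gene prioritization for bulk RNA-seq studies that
    compare three experimental groups on an FPKM expression matrix.
    Implements per-gene z-scored log2 preprocessing, principal coordinate
    ordination of samples, a Welch-test differential-expression screen with
    Benjamini-Hochberg adjustment, two-block partial least squares
    discriminant analysis (PLS-DA) with per-gene Axis-1 Pearson correlation
    ranking and candidate selection against gene annotations, classification
    of expression trajectories across a control / treatment / withdrawal
    timeline, a coexpression screen against an analytic critical-correlation
    threshold, and hypergeometric over-representation analysis of gene sets.
    A synthetic-data generator with planted effects and ground truth supports
    calibration and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
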