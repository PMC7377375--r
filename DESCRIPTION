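Package: dreamgraph
Title: Non-Semantic Word-Graph Analysis of Dream Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the structural analysis of oral dream-report
    transcripts as directed non-semantic word graphs.  Transcripts are
    tokenized with paragraph awareness and converted to graphs in which
    each unique word is a node and each observed word-to-word transition
    a directed edge.  Connectedness measures (number of distinct edges,
    largest connected component, largest strongly connected component)
    are computed over fixed-length sliding windows to control for report
    length, and random-likeness z-scores are obtained against a null
    distribution built from word-order shuffles.  The package also
    implements the statistical comparison pipeline used with such
    measures in sleep research: participant-median Wilcoxon signed-rank
    tests with effect sizes, binomial and Gaussian mixed models,
    proportional-odds cumulative-link models with an optional random
    intercept, likelihood-ratio tests, Nagelkerke pseudo-R-squared, and
    bottom-up hierarchical model-comparison ledgers.  A synthetic
    dream-report corpus generator with known ground truth supports
    calibration and power studies of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
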