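Package: coocnet
Title: Co-Occurrence Association Networks from Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted co-occurrence networks from long-format survey
    responses (participants reporting social identities and the behaviours
    attached to them) using the Simple Ratio Index, characterizes their
    structure (density, coefficient of variation of edge weights, weighted
    betweenness, walktrap communities and Newman modularity), and tests
    non-randomness with datastream (checkerboard-swap) permutations, both
    globally and per dyad (preferred/avoided associates), plus Mantel matrix
    correlations between networks. Includes a synthetic survey generator with
    controllable planted structure for calibration and power studies, and a
    one-call pipeline that reproduces the full analysis on any input dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
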