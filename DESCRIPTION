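Package: signedbalance
Title: Structural Balance Analysis of Signed Networks with
    Signed-Degree-Preserving Null Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing structural balance in undirected signed
    networks. Provides an exact census of all 35 signed three- and four-node
    graphlets (triangle, square, squareZ and squareX families, in induced
    graphlet or non-induced motif mode), enrichment statistics (z-scores,
    fold changes and empirical P values) against four randomization schemes
    - degree-preserving rewiring, signed rewiring, sign shuffling, and a
    maximum-entropy null model that preserves the network topology exactly
    while matching every node's expected signed degree - together with
    generative reference networks (a strongly balanced two-group
    configuration model and an edge-copying growth model) that serve as
    ground truth for validating the null models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
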