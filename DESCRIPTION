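Package: cardiobn
Title: Boolean Network Models of Heart-Field-Specific Cardiomyocyte
    Differentiation
Version: 0.1.0
Authors@R: person("Quantitative Biology", "Maintainer",
    email = "maintainer@example.org", role = c("aut", "cre"))
Description: Asynchronous Boolean network analysis of cardiac gene
    regulatory networks. Ships three curated models of cardiomyocyte
    differentiation (a cardiomyocyte-subtype network, a heart-field
    specification network, and their unified 21-node integration) together
    with a general engine for attractor detection via terminal strongly
    connected components, in-silico knockout and overexpression screening,
    Markov-chain absorption simulation of heterogeneous cell populations,
    and a continuous Boolean network extension for dose-response analysis
    of retinoic acid signaling. Models are interchanged in the BoolNet
    '.bnet' rule format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
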