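Package: reddsim
Title: Relative-Entropy Node Similarity and Link Prediction in Weighted Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Node-similarity measures for undirected weighted graphs built on
    the relative entropy of distance distributions (REDD). Each node is summarised
    by a structural-weight triple combining its degree and strength; Euclidean
    distances between triples are normalised into per-node probability
    distributions, reduced to the top-d most important nodes, and compared with a
    symmetrised Kullback-Leibler divergence to yield a similarity matrix. Also
    provides seven benchmark indices (common neighbours, Adamic-Adar and their
    weighted forms, local random walk, and two further relative-entropy indices),
    mutual-most-similar-node mining, link-prediction AUC over random train/probe
    splits, readers and writers for weighted edge lists, Pajek and adjacency CSV,
    and a Newman-Watts small-world generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
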