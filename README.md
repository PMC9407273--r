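# reddsim

Node-similarity measurement and link prediction for **undirected weighted
graphs**, built around the relative entropy of distance distributions
(REDD) similarity index, for network scientists and systems biologists who
work with weighted interaction data (food webs, neural wiring, transport
and communication networks).

## The method

Classical similarity indices use either a node's degree `k_x` or its
strength `s_x`. REDD combines both. Every node is summarised by a
structural-weight triple

    uw(x) = s_x / k_x
    dw(x) = k_x^2 / (Σ_y k_y) · 1 / s_x
    sw(x) = s_x^2 / (Σ_y s_y) · 1 / k_x

and treated as a point in 3-space. Euclidean distances between triples are
normalised into per-node probability vectors `p(x, y) = 1 − d(x, y) / Σ_y
d(x, y)`, restricted to the common support of the top-*d* nodes by unit
weight and renormalised. Node pairs are compared with the symmetrised
base-2 Kullback–Leibler divergence `d_xy = (KL(p̂_x‖p̂_y) + KL(p̂_y‖p̂_x))/2`
(zero terms contribute 0) and mapped to a similarity

    s_xy = 1 − d_xy / d_max  ∈ [0, 1].

The package also provides:

* seven benchmark indices — CN, WCN, AA, WAA, LRW (3-step local random
  walk), RE-LRW and LRE — behind one dispatcher, `similarity_index()`;
* two evaluation protocols — the mutual-most-similar-node ratio
  (`mutual_most_similar_ratio()`) and link-prediction AUC over random
  train/probe splits (`split_edges()`, `auc_sampled()`, `auc_exact()`,
  `run_experiment()`);
* readers/writers for weighted edge lists, Pajek `.net` and adjacency CSV,
  plus `topology_stats()`;
* a Newman–Watts small-world generator with pluggable edge-weight models
  (`nw_small_world()`, `assign_weights()`, `nw_suite()`), so every
  pipeline is testable without external data;
* a thin command-line front end (`inst/cli/reddsim.R`) over the exported
  `cmd_similarity() / cmd_evaluate() / cmd_synth() / cmd_stats()` workflow
  functions.

## Worked example

```r
library(reddsim)

# a 100-node Newman–Watts small-world graph with uniform-integer weights
g <- assign_weights(nw_small_world(n = 100, M = 2, P = 0.05, seed = 42),
                    "uniform-integer", seed = 43, wmax = 165)
topology_stats(g)
#> n = 100, m = 445, <k> = 8.9000, <s> = 741.5800, <c> = 0.1717, <c_w> = 0.1735 (barrat), rho = 0.0899

S <- redd_similarity(g, d = 5)
mutual_most_similar_ratio(S)
#> [1] 0.64

run_experiment(g, "wcn", metric = "auc", replicates = 5, r = 10000, base_seed = 1)
#> AUC(wcn, d = 5) = 0.6452 over 5 replicate(s)
run_experiment(g, "redd", metric = "auc", d = 5, replicates = 5, r = 10000, base_seed = 1)
#> AUC(redd, d = 5) = 0.4875 over 5 replicate(s)
```

Reading the numbers: 64% of nodes belong to a mutually-most-similar pair
under REDD — high, because REDD avoids the "general similar node" collapse
that makes degree-driven indices pick the same hub for everyone
(`most_similar_pairs()` flags such hubs). The AUC lines score each index on
held-out edges: weighted common neighbours carry real signal on this graph
(0.65), while REDD's pure node-attribute similarity is near chance on
i.i.d.-weighted synthetic topologies — see the methods vignette
(`vignettes/redd-similarity.Rmd`) for why, and for every modelling and
numerical decision.

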