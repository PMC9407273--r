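---
title: "Relative-entropy node similarity in weighted graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative-entropy node similarity in weighted graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reddsim)
```

## The problem

Many real networks — protein interaction maps, food webs, neural wiring,
air-transport systems — carry edge weights, and two questions recur when
analysing them: *which node is most like this one?* (most-similar-node
mining) and *which unobserved pairs are most likely to be true edges?*
(link prediction). Classical similarity indices answer these using only the
degree `k_x` (number of incident edges) or only the strength
`s_x` (sum of incident weights). The REDD index implemented here combines
both, on the view that degree reflects a node's capacity to *diffuse*
information while strength reflects its capacity to *collect* it.

## The REDD construction

Each node is summarised by a **structural-weight triple**:

* unit weight `uw(x) = s_x / k_x`, the mean incident edge weight;
* degree weight `dw(x) = k_x^2 / (sum_y k_y) * 1 / s_x`, degree-dominant
  with strength suppressed;
* strength weight `sw(x) = s_x^2 / (sum_y s_y) * 1 / k_x`, the mirror image.

Both sums run over all `n` nodes, including `x` itself. On an unweighted
graph (all weights 1) the triple degenerates to `(1, k_x/2m, k_x/2m)`.

Treating triples as points in 3-space, the distance between two nodes is the
Euclidean distance between their triples, and each node `x` gets a
**probability vector** over all nodes,

```
p(x, y) = 1 - d(x, y) / sum_y d(x, y),
```

which is 1 for `y = x`, lies in `[0, 1]`, and sums to `n - 1`. To keep the
divergence computation cheap and focused on influential nodes, every vector
is restricted to the common support of the **top-d nodes by unit weight**
and renormalised to sum 1. Pairs of reduced distributions are compared with
the symmetrised base-2 relative entropy

```
d_xy = (KL(p_x || p_y) + KL(p_y || p_x)) / 2,
```

where any term with a zero on either side contributes 0, and finally mapped
to a similarity in `[0, 1]`:

```
s_xy = 1 - d_xy / d_max.
```

`redd_similarity(g, d)` performs the whole pipeline; the intermediate
operations (`structural_weight_set()`, `distance_distribution()`,
`probability_distribution()`, `top_d_nodes()`, `reduced_distribution()`,
`relative_entropy()`, `pairwise_difference()`) are exported individually so
each stage can be inspected.

```{r}
g <- read_weighted_edge_list(text = c("1 2 1", "2 3 2", "3 4 3"))
structural_weight_set(g)
round(unclass(redd_similarity(g, d = 2)), 4)
```

## Parameters that matter

* **`d`** (top-d support size, default 5, sensible range 2..7): controls how
  many reference nodes anchor the reduced distributions. Results are stable
  across 2..7 in our test networks; `d` may not exceed `n`. The ranking is
  by descending unit weight with ties broken toward the lower node index, so
  runs are exactly reproducible.
* **`t`** (walk length for the random-walk indices, default 3): the
  conventional short-walk horizon; `lrw_index()` and `re_lrw_index()` use
  the degree-based transition matrix `a_xy / k_x` by default, with a
  weight-proportional option (`weighted = TRUE`) for sensitivity checks.
* **Evaluation defaults**: training fraction 0.9, 30 independent splits,
  10,000 sampled AUC comparisons — the standard protocol for this family of
  studies. `auc_exact()` enumerates all probe x unknown pairs and is the
  deterministic expectation of `auc_sampled()`.

## Numerical choices and degenerate inputs

* **Logarithm base.** All divergences use base 2. The per-term zero
  convention (a term with `p = 0` or `q = 0` contributes 0) keeps every
  divergence finite without smoothing constants.
* **Degenerate distance sums.** When every node has the same structural
  triple (any vertex-transitive graph with equal weights: complete graphs,
  cycles, pure ring lattices), `sum_y d(x, y) = 0`; the distance ratio is
  then taken as 0, the probability vectors are all-ones, the reduced forms
  uniform, `d_max = 0`, and the similarity matrix is all ones.
  Indistinguishable nodes are maximally similar.
* **Zero restricted mass.** If a reduced vector sums to 0 it falls back to
  the uniform vector over the support.
* **Isolated nodes** get the zero triple by convention and never enter a
  top-d support; disconnected graphs are accepted throughout (no
  connectivity repair after edge splitting either).
* **Ties.** Most-similar nodes and top-d rankings break ties toward the
  lowest node index, which makes the mutual-most-similar ratio well defined
  on degenerate matrices.
* **Probe-size rounding** is half-up on `(1 - fraction) * m`.
* **Diagonals.** The common-neighbour family and LRW use diagonal 0, the
  relative-entropy family diagonal 1; neither evaluation metric reads the
  diagonal.

## Open design points, and how they were settled

* **Weighted clustering coefficient.** There is no single standard;
  `topology_stats()` offers the Barrat form (default) and the Onnela form.
  Published tables of this statistic often do not state their variant, so
  cross-study comparison of `<c_w>` should be done with care.
* **RE-LRW final mapping.** The RE-LRW baseline is described in the
  literature only up to its relative-entropy difference; this package maps
  the difference to a similarity with the same `1 - d/d_max` transform as
  REDD, for internal consistency.
* **LRE distribution.** The local relative-entropy baseline represents each
  node by the degree histogram of its closed neighbourhood
  `{x} union N(x)`, normalised to a probability vector on the union of
  observed degree values.
* **Self-membership in the support.** A node belonging to the top-d set
  keeps its own unit entry before renormalisation; excluding it is a
  defensible alternative but changes nothing qualitative in our tests.

## The synthetic generator

`nw_small_world(n, M, P, seed)` produces Newman–Watts small-world graphs: a
ring lattice where every node links to its `M` nearest neighbours on each
side (so base degree `2M` and edge count `nM`), plus an independent shortcut
with probability `P` for every non-adjacent pair — addition only, no
rewiring. At `P = 0` the closed forms `m = nM`, `<k> = 2M` and
`<c> = 3(M-1) / (2(2M-1))` hold exactly; shortcut counts are binomial. A
`"total"` variant (base degree `M`) is available since the per-side
convention is not universal. `nw_suite()` instantiates the nine standard
settings `M in {2, 3, 4} x P in {0.01, 0.05, 0.10}` at `n = 100`.

Edge weights are assigned separately (`assign_weights()`), i.i.d. per edge;
the default is uniform integers on `[1, 165]`, chosen once so that the mean
strength of the sparsest setting (`M = 2`, `P = 0.01`) is of the order
reported for comparable simulated networks (`<s> ~ 5e2` at `<k> ~ 6`).
What the generator emulates is the *topology* family used in simulation
studies of this kind — tunable mean degree via `M`, tunable clustering via
`P` — together with positive heterogeneous weights. What it does **not**
emulate is any dependence of weights on structure: real weighted networks
couple weights to topology (traffic concentrates on hubs, strong ties close
triangles), and no i.i.d. model reproduces that. Conclusions drawn from
these fixtures therefore validate the *mechanics* of the indices and
protocols, not their ranking on real data.

## Known limitations

* On i.i.d.-weighted small-world graphs the REDD score, being a pure
  node-attribute similarity, carries almost no edge-presence signal: its
  link-prediction AUC sits near 0.5 there (the end-to-end suite computes
  this), even though its mutual-most-similar ratio is high (~0.7-0.8) and
  far above the common-neighbour family, and even though the pipeline
  reproduces the defining equations to 1e-10 against an independent
  brute-force oracle. Reported large AUC values for attribute-style indices
  on real networks should be read in the light of weight-topology coupling,
  which the i.i.d. generator deliberately lacks.
* Dense-matrix internals: the implementation targets the network sizes this
  method is used at (hundreds to low thousands of nodes); no sparse
  shortcuts are attempted, by design, to keep results exactly reproducible.
* Directed graphs, multigraphs and negative weights are out of scope; arcs
  in Pajek input are symmetrised.

## Problem sizes in the test suite

The automated tests run the oracle-equivalence property on 200 random graphs
with `n` in 4..12, the divergence identities on 1000 random distribution
pairs, the estimator-consistency check on a 60-node small-world network with
50 repeated samplings at `r = 10,000`, the generator statistics on 200
seeds, and the end-to-end eight-index experiment on one `n = 100` network
with 10 replicate splits. These sizes give tight Monte-Carlo error bars for
every assertion while keeping the full suite under a minute.
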