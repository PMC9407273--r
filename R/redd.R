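#' Distances between structural-weight triples
#'
#' Each node is a point `(uw, dw, sw)` in 3-space (see
#' [structural_weight_set()]); the distance between two nodes is the ordinary
#' Euclidean distance between their triples. `distance_distribution()` collects
#' the distances from one node to every node (its own entry is 0).
#'
#' @param sw_set `n x 3` matrix from [structural_weight_set()].
#' @param x,y internal node indices.
#' @return `node_distance()` a single nonnegative number;
#'   `distance_distribution()` a length-`n` numeric vector.
#' @export
node_distance <- function(sw_set, x, y) {
  sqrt(sum((sw_set[x, ] - sw_set[y, ])^2))
}

#' @rdname node_distance
#' @export
distance_distribution <- function(sw_set, x) {
  sqrt(colSums((t(sw_set) - sw_set[x, ])^2))
}

#' Probability distribution of a node
#'
#' Normalises a distance distribution into pseudo-probabilities of an edge:
#' `p(x, y) = 1 - d(x, y) / sum_y d(x, y)`. Every entry lies in `[0, 1]`, the
#' self entry is exactly 1, and the entries sum to `n - 1`. When all distances
#' are zero (every node has the same structural triple) the ratio is taken as
#' 0 by convention, giving the all-ones vector: indistinguishable nodes are
#' maximally similar.
#'
#' @param dd numeric vector of distances (length `n >= 2`).
#' @return numeric vector of length `n`.
#' @export
probability_distribution <- function(dd) {
  total <- sum(dd)
  if (total == 0) return(rep(1, length(dd)))
  1 - dd / total
}

#' Top-d important nodes by unit weight
#'
#' Ranks nodes by descending unit weight, breaking ties by ascending node
#' index, and returns the first `d` indices. Isolated nodes (unit weight 0 by
#' convention) are excluded from the ranking, so fewer than `d` members are
#' returned when the graph has fewer than `d` non-isolated nodes.
#'
#' @param sw_set `n x 3` matrix from [structural_weight_set()].
#' @param d number of nodes to keep, `1 <= d <= n`.
#' @return integer vector of node indices, ordered by rank.
#' @export
top_d_nodes <- function(sw_set, d) {
  n <- nrow(sw_set)
  if (d < 1 || d > n) stop("d must lie in [1, n], got d = ", d, ", n = ", n)
  uw <- sw_set[, "uw"]
  ord <- order(-uw, seq_len(n))          # descending uw, ascending index on ties
  ord <- ord[uw[ord] > 0]                # drop isolated nodes
  utils::head(ord, d)
}

#' Reduce a probability distribution to a top-d support
#'
#' Restricts a full per-node probability vector to the top-d node set and
#' renormalises it to sum 1. If the restricted mass is zero the uniform
#' distribution over the support is returned.
#'
#' @param pd full probability vector (length `n`).
#' @param top integer vector of support indices (see [top_d_nodes()]).
#' @return numeric vector of length `length(top)` summing to 1.
#' @export
reduced_distribution <- function(pd, top) {
  v <- pd[top]
  s <- sum(v)
  if (s == 0) return(rep(1 / length(top), length(top)))
  v / s
}

#' Relative entropy (Kullback-Leibler divergence), base 2
#'
#' `relative_entropy(p, q)` is `sum_z p_z * log2(p_z / q_z)` where any term
#' with `p_z = 0` or `q_z = 0` contributes 0 (the zero convention used
#' throughout the package). It is asymmetric; `symmetrized_kl()` averages the
#' two directions, `(KL(p||q) + KL(q||p)) / 2`, which is symmetric and equals
#' the single-sum form `sum_z (p_z - q_z) * log2(p_z / q_z) / 2`.
#'
#' @param p,q numeric vectors on the same support, same length.
#' @return a single numeric value (finite by the zero convention).
#' @export
relative_entropy <- function(p, q) {
  if (length(p) != length(q)) {
    stop("distributions must share a support: lengths ", length(p), " vs ", length(q))
  }
  keep <- p > 0 & q > 0
  sum(p[keep] * log2(p[keep] / q[keep]))
}

#' @rdname relative_entropy
#' @export
symmetrized_kl <- function(p, q) {
  (relative_entropy(p, q) + relative_entropy(q, p)) / 2
}

#' Difference between two nodes' reduced distributions
#'
#' The symmetrised relative entropy between the reduced distributions of two
#' nodes: `d_xy = (RE(x, y) + RE(y, x)) / 2`. Symmetric, with `d_xx = 0`.
#'
#' @param reduced matrix whose rows are reduced distributions on a common
#'   top-d support (one row per node).
#' @param x,y node indices (rows of `reduced`).
#' @return a single nonnegative number.
#' @export
pairwise_difference <- function(reduced, x, y) {
  symmetrized_kl(reduced[x, ], reduced[y, ])
}

## RE[x, y] = KL(p[x, ] || p[y, ]) for all ordered pairs, zero convention,
## accumulated column-by-column (d is small, n^2 outer products are cheap)
kl_divergence_matrix <- function(p) {
  n <- nrow(p)
  lp <- matrix(0, n, ncol(p))
  pos <- p > 0
  lp[pos] <- log2(p[pos])
  RE <- matrix(0, n, n)
  for (z in seq_len(ncol(p))) {
    pz <- p[, z]
    lz <- lp[, z]
    term <- (pz * lz) %o% rep(1, n) - pz %o% lz
    term[!((pz > 0) %o% (pz > 0))] <- 0
    RE <- RE + term
  }
  RE
}

#' REDD similarity matrix
#'
#' The package's core index: relative entropy of distance distributions.
#' The pipeline is
#'
#' 1. structural-weight triples `(uw, dw, sw)` for every node;
#' 2. pairwise Euclidean distances between triples and, per node, the
#'    normalised probability vector `p(x, y) = 1 - d(x, y) / sum_y d(x, y)`;
#' 3. restriction of every probability vector to the common support of the
#'    top-`d` nodes by unit weight, renormalised to sum 1;
#' 4. symmetrised base-2 relative entropy between every pair of reduced
#'    distributions, `d_xy`;
#' 5. similarity `s_xy = 1 - d_xy / d_max`, where `d_max` is the largest
#'    pairwise difference.
#'
#' The result is symmetric with entries in `[0, 1]` and unit diagonal. When
#' every node has the same structural triple, `d_max = 0` and the all-ones
#' matrix is returned. Nodes in the same automorphism orbit always receive
#' similarity 1. A node belonging to the top-`d` support keeps its own
#' unit self-entry before renormalisation.
#'
#' @param g a `weighted_graph` with `n >= 2` nodes.
#' @param d size of the top-d support, `1 <= d <= n`; default 5. Values in
#'   2..7 are the usual operating range.
#' @return a `similarity_matrix` with `index = "redd"`.
#' @examples
#' g <- read_weighted_edge_list(text = c("1 2 1", "2 3 2", "3 4 3"))
#' redd_similarity(g, d = 2)
#' @export
redd_similarity <- function(g, d = 5) {
  n <- n_nodes(g)
  if (n < 2) stop("need at least 2 nodes")
  if (d < 1 || d > n) stop("d must lie in [1, n], got d = ", d, ", n = ", n)
  sa <- structural_weight_set(g)
  D <- as.matrix(stats::dist(sa))
  rs <- rowSums(D)
  P <- matrix(1, n, n)                   # rows with all-zero distances stay 1
  nz <- rs > 0
  if (any(nz)) P[nz, ] <- 1 - D[nz, , drop = FALSE] / rs[nz]
  top <- top_d_nodes(sa, d)
  R <- P[, top, drop = FALSE]
  mass <- rowSums(R)
  phat <- R / ifelse(mass > 0, mass, 1)
  if (any(mass == 0)) phat[mass == 0, ] <- 1 / length(top)
  RE <- kl_divergence_matrix(phat)
  dxy <- (RE + t(RE)) / 2
  diag(dxy) <- 0
  dmax <- max(dxy)
  S <- if (dmax == 0) matrix(1, n, n) else 1 - dxy / dmax
  diag(S) <- 1
  similarity_matrix(S, "redd", g$labels)
}
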