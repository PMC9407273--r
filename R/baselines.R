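#' Benchmark similarity indices
#'
#' Seven standard node-similarity indices used as baselines for
#' [redd_similarity()]:
#'
#' * `cn_index()` — common neighbours: `s_xy = |N(x) intersect N(y)|`;
#' * `wcn_index()` — weighted CN: `s_xy = sum_z (w_xz + w_yz)` over common
#'   neighbours `z`;
#' * `aa_index()` — Adamic-Adar: `s_xy = sum_z 1 / log(k_z)`;
#' * `waa_index()` — weighted AA: `s_xy = sum_z (w_xz + w_yz) / log(1 + s_z)`
#'   (the `1 +` keeps the denominator positive when strengths fall below 1);
#' * `lrw_index()` — local random walk, see below;
#' * `re_lrw_index()` — relative entropy of local-random-walk transition
#'   distributions;
#' * `lre_index()` — local relative entropy of closed-neighbourhood degree
#'   distributions.
#'
#' The CN family and LRW use diagonal 0; the relative-entropy family uses
#' diagonal 1. Neither evaluation protocol ever reads the diagonal.
#'
#' @param g a `weighted_graph`.
#' @param log_base logarithm base for the AA/WAA denominators; natural log by
#'   default, the conventional choice.
#' @return a `similarity_matrix`.
#' @name baseline_indices
NULL

#' @rdname baseline_indices
#' @export
cn_index <- function(g) {
  A <- adjacency(g)
  S <- A %*% A
  diag(S) <- 0
  similarity_matrix(S, "cn", g$labels)
}

#' @rdname baseline_indices
#' @export
wcn_index <- function(g) {
  A <- adjacency(g)
  W <- g$w
  S <- W %*% A + A %*% W
  diag(S) <- 0
  similarity_matrix(S, "wcn", g$labels)
}

#' @rdname baseline_indices
#' @export
aa_index <- function(g, log_base = exp(1)) {
  A <- adjacency(g)
  k <- rowSums(A)
  coef <- ifelse(k >= 2, 1 / (log(k) / log(log_base)), 0)  # k<2 never a common neighbour
  S <- A %*% (coef * A)
  diag(S) <- 0
  similarity_matrix(S, "aa", g$labels)
}

#' @rdname baseline_indices
#' @export
waa_index <- function(g, log_base = exp(1)) {
  A <- adjacency(g)
  W <- g$w
  s <- rowSums(W)
  coef <- ifelse(s > 0, 1 / (log(1 + s) / log(log_base)), 0)
  S <- W %*% (coef * A) + A %*% (coef * W)
  diag(S) <- 0
  similarity_matrix(S, "waa", g$labels)
}

## row-stochastic transition matrix; isolated nodes get a self-loop row.
## unweighted walk (a_xy / k_x) by default, weighted (w_xy / s_x) behind a flag
transition_matrix <- function(g, weighted = FALSE) {
  M <- if (weighted) g$w else adjacency(g)
  rs <- rowSums(M)
  P <- M / ifelse(rs > 0, rs, 1)
  iso <- rs == 0
  if (any(iso)) P[cbind(which(iso), which(iso))] <- 1
  P
}

mat_power <- function(P, t) {
  out <- P
  for (i in seq_len(t - 1)) out <- out %*% P
  out
}

#' @rdname baseline_indices
#' @param t walk length (number of steps); default 3.
#' @param weighted if `TRUE` the walk uses weight-proportional transition
#'   probabilities `w_xy / s_x` instead of the default degree-based
#'   `a_xy / k_x`.
#' @export
lrw_index <- function(g, t = 3, weighted = FALSE) {
  if (t < 1) stop("walk length t must be >= 1")
  k <- as.numeric(degrees(g))
  m <- n_edges(g)
  Pi <- mat_power(transition_matrix(g, weighted), t)  # Pi[x, y] = pi_xy(t)
  half <- (k / (2 * m)) * Pi
  S <- half + t(half)
  diag(S) <- 0
  similarity_matrix(S, "lrw", g$labels)
}

## shared tail of the relative-entropy indices: rows of `p` are per-node
## distributions on a common support -> symmetrised KL -> 1 - d/dmax
entropy_similarity <- function(p, labels, index) {
  RE <- kl_divergence_matrix(p)
  dxy <- (RE + t(RE)) / 2
  diag(dxy) <- 0
  dmax <- max(dxy)
  S <- if (dmax == 0) matrix(1, nrow(p), nrow(p)) else 1 - dxy / dmax
  diag(S) <- 1
  similarity_matrix(S, index, labels)
}

#' @rdname baseline_indices
#' @param d size of the top-d support (by degree centrality for
#'   `re_lrw_index()`); default 5.
#' @export
re_lrw_index <- function(g, d = 5, t = 3, weighted = FALSE) {
  n <- n_nodes(g)
  if (n < 2) stop("need at least 2 nodes")
  if (d < 1 || d > n) stop("d must lie in [1, n], got d = ", d, ", n = ", n)
  if (t < 1) stop("walk length t must be >= 1")
  k <- as.numeric(degrees(g))
  ord <- order(-k, seq_len(n))
  ord <- ord[k[ord] > 0]
  top <- utils::head(ord, d)
  Pi <- mat_power(transition_matrix(g, weighted), t)
  R <- Pi[, top, drop = FALSE]
  mass <- rowSums(R)
  phat <- R / ifelse(mass > 0, mass, 1)
  if (any(mass == 0)) phat[mass == 0, ] <- 1 / length(top)
  entropy_similarity(phat, g$labels, "re-lrw")
}

#' @rdname baseline_indices
#' @export
lre_index <- function(g) {
  n <- n_nodes(g)
  if (n < 2) stop("need at least 2 nodes")
  k <- as.numeric(degrees(g))
  support <- sort(unique(k))
  A <- adjacency(g)
  p <- matrix(0, n, length(support))
  for (x in seq_len(n)) {
    members <- c(x, which(A[x, ] > 0))
    tab <- tabulate(match(k[members], support), nbins = length(support))
    p[x, ] <- tab / length(members)
  }
  entropy_similarity(p, g$labels, "lre")
}

#' Compute a similarity matrix by index name
#'
#' Front door used by the evaluation harness and the command-line interface:
#' dispatches to one of the eight indices by name.
#'
#' @param g a `weighted_graph`.
#' @param index one of `"redd"`, `"cn"`, `"wcn"`, `"aa"`, `"waa"`, `"lrw"`,
#'   `"re-lrw"`, `"lre"`.
#' @param d top-d support size for `"redd"` and `"re-lrw"`.
#' @param t walk length for `"lrw"` and `"re-lrw"`.
#' @param ... further arguments passed to the index function.
#' @return a `similarity_matrix`.
#' @export
similarity_index <- function(g, index = c("redd", "cn", "wcn", "aa", "waa",
                                          "lrw", "re-lrw", "lre"),
                             d = 5, t = 3, ...) {
  index <- match.arg(index)
  switch(index,
    "redd"   = redd_similarity(g, d = d),
    "cn"     = cn_index(g),
    "wcn"    = wcn_index(g),
    "aa"     = aa_index(g, ...),
    "waa"    = waa_index(g, ...),
    "lrw"    = lrw_index(g, t = t, ...),
    "re-lrw" = re_lrw_index(g, d = d, t = t, ...),
    "lre"    = lre_index(g)
  )
}
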