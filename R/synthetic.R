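#' Newman-Watts small-world topology
#'
#' Builds a ring lattice on `n` nodes where each node is joined to its `M`
#' nearest neighbours on each side (base degree `2M`, base edge count `nM`),
#' then adds a shortcut between each non-adjacent pair independently with
#' probability `P`. Unlike the Watts-Strogatz model no edges are rewired or
#' removed, so the lattice backbone is always present. Edge weights are 1;
#' use [assign_weights()] to draw weights.
#'
#' With `P = 0` the closed forms hold exactly: `m = nM`, every degree `2M`,
#' mean clustering `3(M - 1) / (2(2M - 1))`. The expected shortcut count is
#' `P * (n(n-1)/2 - nM)`.
#'
#' @param n number of nodes; at least 3 (default 100, the usual simulation
#'   size).
#' @param M lattice neighbourhood radius; must satisfy `M < n / 2`.
#' @param P shortcut probability in `[0, 1]`.
#' @param seed integer seed; the topology is deterministic given the seed.
#' @param variant `"per-side"` (default; each node linked to `M` neighbours
#'   on each side) or `"total"` (base degree `M`; requires even `M`).
#' @return a `weighted_graph` with unit weights.
#' @examples
#' g <- nw_small_world(n = 20, M = 2, P = 0, seed = 1)
#' n_edges(g)  # exactly n * M
#' @export
nw_small_world <- function(n = 100, M = 2, P = 0.01, seed,
                           variant = c("per-side", "total")) {
  variant <- match.arg(variant)
  if (n < 3) stop("n must be >= 3")
  if (M < 1) stop("M must be >= 1")
  if (P < 0 || P > 1) stop("P must lie in [0, 1]")
  radius <- if (variant == "per-side") M else {
    if (M %% 2 != 0) stop("variant 'total' requires an even M")
    M / 2
  }
  if (radius >= n / 2) stop("M too large: lattice would be complete (need M < n/2)")
  w <- matrix(0, n, n)
  for (j in seq_len(radius)) {
    i <- seq_len(n)
    nb <- ((i - 1 + j) %% n) + 1
    w[cbind(i, nb)] <- 1
    w[cbind(nb, i)] <- 1
  }
  if (P > 0) {
    set.seed(seed)
    cand <- which(upper.tri(w) & w == 0)
    add <- cand[stats::runif(length(cand)) < P]
    w[add] <- 1
    w <- pmax(w, t(w))
  }
  weighted_graph(w)
}

#' Assign random edge weights
#'
#' Draws one i.i.d. positive weight per edge of an existing topology, in the
#' canonical edge order of [edge_table()], so the result is deterministic for
#' a given seed. Models:
#'
#' * `"uniform-integer"` — integers uniform on `1..wmax` (default,
#'   `wmax = 165`);
#' * `"uniform-real"` — uniform on `(min, max)`;
#' * `"lognormal"` — log-normal with `meanlog`, `sdlog`;
#' * `"constant"` — every weight equal to `value` (strengths then equal
#'   `value` times degrees).
#'
#' @param g a `weighted_graph` (weights are replaced).
#' @param model weight model name.
#' @param seed integer seed.
#' @param wmax upper bound for `"uniform-integer"`.
#' @param min,max range for `"uniform-real"`.
#' @param meanlog,sdlog parameters for `"lognormal"`.
#' @param value weight for `"constant"`.
#' @return a `weighted_graph` with the same topology and new weights.
#' @export
assign_weights <- function(g, model = c("uniform-integer", "uniform-real",
                                        "lognormal", "constant"),
                           seed, wmax = 165, min = 0.5, max = 1.5,
                           meanlog = 0, sdlog = 1, value = 1) {
  model <- match.arg(model)
  et <- edge_table(g)
  m <- nrow(et)
  if (model != "constant") set.seed(seed)
  wts <- switch(model,
    "uniform-integer" = {
      if (wmax < 1) stop("wmax must be >= 1")
      sample.int(wmax, m, replace = TRUE)
    },
    "uniform-real" = {
      if (min <= 0 || max <= min) stop("need 0 < min < max")
      stats::runif(m, min, max)
    },
    "lognormal" = stats::rlnorm(m, meanlog, sdlog),
    "constant" = {
      if (value <= 0) stop("constant weight must be positive")
      rep(value, m)
    }
  )
  w <- matrix(0, n_nodes(g), n_nodes(g))
  w[cbind(et$i, et$j)] <- wts
  w[cbind(et$j, et$i)] <- wts
  weighted_graph(w, g$labels)
}

## the nine standard (M, P) simulation settings at n = 100
nw_suite_params <- function() {
  data.frame(
    name = paste0("net", 1:9),
    M = rep(c(2, 3, 4), each = 3),
    P = rep(c(0.01, 0.05, 0.10), times = 3),
    stringsAsFactors = FALSE
  )
}

#' Generate the nine-network simulation suite
#'
#' Builds the standard nine weighted small-world networks used for
#' simulation studies: every combination of `M` in 2, 3, 4 and `P` in 0.01,
#' 0.05, 0.10 at `n = 100`, weighted with the default uniform-integer model.
#' Network `i` uses seed `seed + i` for its topology and `seed + 100 + i` for
#' its weights, so the whole suite is reproducible from one seed.
#'
#' @param seed integer base seed.
#' @param n nodes per network; default 100.
#' @param weight_model,wmax passed to [assign_weights()].
#' @return a named list (`net1` ... `net9`); each element is a list with the
#'   `graph`, its generation parameters `M`, `P` and its [topology_stats()].
#'   The manifest of parameters and achieved statistics is attached as the
#'   `manifest` attribute (a data frame).
#' @export
nw_suite <- function(seed, n = 100, weight_model = "uniform-integer",
                         wmax = 165) {
  params <- nw_suite_params()
  nets <- vector("list", nrow(params))
  names(nets) <- params$name
  rows <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    topo <- nw_small_world(n = n, M = params$M[i], P = params$P[i],
                           seed = seed + i)
    gw <- assign_weights(topo, model = weight_model, seed = seed + 100 + i,
                         wmax = wmax)
    st <- topology_stats(gw)
    nets[[i]] <- list(graph = gw, M = params$M[i], P = params$P[i], stats = st)
    rows[[i]] <- cbind(data.frame(network = params$name[i], M = params$M[i],
                                  P = params$P[i]), as.data.frame(st))
  }
  attr(nets, "manifest") <- do.call(rbind, rows)
  nets
}
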