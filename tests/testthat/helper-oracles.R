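# Fixture generators and independent brute-force oracles used across tests.
# The oracles are deliberately written as plain scalar loops, separate from
# the vectorised production code paths.

rand_wgraph <- function(n, p = 0.5, wmax = 5, seed = 1, integer_weights = FALSE) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (x in seq_len(n - 1)) {
    for (y in (x + 1):n) {
      if (stats::runif(1) < p) {
        wt <- if (integer_weights) sample.int(wmax, 1) else round(stats::runif(1, 0.1, wmax), 3)
        w[x, y] <- wt
        w[y, x] <- wt
      }
    }
  }
  if (sum(w) == 0) w[1, 2] <- w[2, 1] <- 1
  weighted_graph(w)
}

rand_unweighted_graph <- function(n, p = 0.5, seed = 1) {
  g <- rand_wgraph(n, p, seed = seed)
  weighted_graph((weight_matrix(g) > 0) + 0)
}

# per-node degree/strength recomputed by explicit summation
brute_degree_strength <- function(g) {
  w <- weight_matrix(g)
  n <- nrow(w)
  k <- numeric(n); s <- numeric(n)
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      if (w[x, y] > 0) k[x] <- k[x] + 1
      s[x] <- s[x] + w[x, y]
    }
  }
  list(k = k, s = s)
}

naive_kl <- function(p, q) {
  acc <- 0
  for (z in seq_along(p)) {
    if (p[z] > 0 && q[z] > 0) acc <- acc + p[z] * log2(p[z] / q[z])
  }
  as.numeric(acc)
}

# the whole REDD pipeline re-derived with scalar loops
naive_redd <- function(g, d) {
  w <- weight_matrix(g)
  n <- nrow(w)
  ks <- brute_degree_strength(g)
  k <- ks$k; s <- ks$s
  uw <- ifelse(k > 0, s / k, 0)
  dw <- ifelse(k > 0, k^2 / sum(k) / s, 0)
  sw <- ifelse(k > 0, s^2 / sum(s) / k, 0)
  dmat <- matrix(0, n, n)
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      dmat[x, y] <- sqrt((uw[x] - uw[y])^2 + (dw[x] - dw[y])^2 + (sw[x] - sw[y])^2)
    }
  }
  p <- matrix(1, n, n)
  for (x in seq_len(n)) {
    tot <- sum(dmat[x, ])
    if (tot > 0) for (y in seq_len(n)) p[x, y] <- 1 - dmat[x, y] / tot
  }
  ord <- order(-uw, seq_len(n))
  ord <- ord[uw[ord] > 0]
  top <- ord[seq_len(min(d, length(ord)))]
  ph <- matrix(0, n, length(top))
  for (x in seq_len(n)) {
    v <- p[x, top]
    ph[x, ] <- if (sum(v) == 0) rep(1 / length(top), length(top)) else v / sum(v)
  }
  RE <- matrix(0, n, n)
  for (x in seq_len(n)) for (y in seq_len(n)) RE[x, y] <- naive_kl(ph[x, ], ph[y, ])
  dd <- (RE + t(RE)) / 2
  diag(dd) <- 0
  dmax <- max(dd)
  S <- if (dmax == 0) matrix(1, n, n) else 1 - dd / dmax
  diag(S) <- 1
  S
}

# set-intersection oracles for the local indices
brute_cn <- function(g, x, y) {
  A <- adjacency(g)
  length(intersect(which(A[x, ] > 0), which(A[y, ] > 0)))
}

brute_wcn <- function(g, x, y) {
  w <- weight_matrix(g)
  z <- intersect(which(w[x, ] > 0), which(w[y, ] > 0))
  sum(w[x, z] + w[y, z])
}

brute_aa <- function(g, x, y) {
  A <- adjacency(g)
  k <- rowSums(A)
  z <- intersect(which(A[x, ] > 0), which(A[y, ] > 0))
  sum(1 / log(k[z]))
}

brute_waa <- function(g, x, y) {
  w <- weight_matrix(g)
  s <- rowSums(w)
  z <- intersect(which(w[x, ] > 0), which(w[y, ] > 0))
  sum((w[x, z] + w[y, z]) / log(1 + s[z]))
}

# 10-node similarity structure in which v1 and v2 are each other's unique
# most similar node and no other pair is reciprocated
ms_worked_example <- function() {
  s <- matrix(0, 10, 10)
  for (x in 3:9) s[x, x + 1] <- s[x + 1, x] <- x   # strict preference chain
  s[10, 1] <- s[1, 10] <- 9.5                      # breaks the (9, 10) pair
  s[1, 2] <- s[2, 1] <- 20                         # the one mutual pair
  similarity_matrix(s, "toy")
}

# random probability vector on the simplex
rand_distribution <- function(d) {
  v <- stats::runif(d)
  v / sum(v)
}
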