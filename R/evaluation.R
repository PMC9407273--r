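#' Split observed edges into training and probe sets
#'
#' Partitions the edge set `E` uniformly at random into a training set `E_t`
#' and probe set `E_p` with `E_t union E_p = E` and `E_t intersect E_p`
#' empty. The probe size is `round_half_up((1 - train_fraction) * m)`. The
#' training graph keeps every node (probe endpoints may become isolated; no
#' connectivity repair is attempted). The universe of unknown edges —
#' unordered node pairs not adjacent in the *original* graph — is recorded so
#' link-prediction AUC can compare probe scores against it.
#'
#' @param g a `weighted_graph` with at least 2 edges.
#' @param train_fraction fraction of edges kept for training, in (0, 1);
#'   default 0.9.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return an object of class `link_split`: a list with elements
#'   `train_graph` (a `weighted_graph` on all nodes), `train`, `probe`
#'   (edge data frames as in [edge_table()]), `unknown` (data frame of
#'   non-adjacent pairs `i`, `j`), `train_fraction`, `seed`.
#' @export
split_edges <- function(g, train_fraction = 0.9, seed) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  et <- edge_table(g)
  m <- nrow(et)
  if (m < 2) stop("need at least 2 edges to split")
  n_probe <- floor((1 - train_fraction) * m + 0.5)   # round half up
  if (n_probe == 0) stop("train_fraction ", train_fraction, " leaves an empty probe set")
  if (n_probe == m) stop("train_fraction ", train_fraction, " leaves an empty training set")
  set.seed(seed)
  probe_rows <- sort(sample.int(m, n_probe))
  probe <- et[probe_rows, , drop = FALSE]
  train <- et[-probe_rows, , drop = FALSE]
  wt <- g$w
  wt[cbind(probe$i, probe$j)] <- 0
  wt[cbind(probe$j, probe$i)] <- 0
  train_graph <- weighted_graph(wt, g$labels)
  ut <- which(upper.tri(g$w) & g$w == 0, arr.ind = TRUE)
  unknown <- data.frame(i = ut[, 1], j = ut[, 2])
  structure(
    list(train_graph = train_graph, train = train, probe = probe,
         unknown = unknown, train_fraction = train_fraction, seed = seed),
    class = "link_split"
  )
}

#' @export
print.link_split <- function(x, ...) {
  cat(sprintf("link_split: %d training edges, %d probe edges, %d unknown pairs (seed %d)\n",
              nrow(x$train), nrow(x$probe), nrow(x$unknown), x$seed))
  invisible(x)
}

## index of each node's most similar other node; ties -> lowest index
most_similar_vector <- function(sim) {
  s <- unclass_sim(sim)
  diag(s) <- -Inf
  apply(s, 1, which.max)     # which.max takes the first maximum: lowest index
}

#' Mutual-most-similar-node ratio (MS)
#'
#' For each node `x` let `ms(x)` be the node (other than `x`) with the
#' highest similarity to `x`, ties broken towards the lowest index. Nodes `x`
#' and `y` are mutually most similar when `ms(x) = y` and `ms(y) = x`. MS is
#' the fraction of nodes belonging to such a pair; the count is always even.
#'
#' @param sim a `similarity_matrix` (at least 2 nodes).
#' @return a number in `[0, 1]`, always a multiple of `2 / n`.
#' @export
mutual_most_similar_ratio <- function(sim) {
  n <- nrow(sim)
  if (n < 2) stop("need at least 2 nodes")
  ms <- most_similar_vector(sim)
  mutual <- ms[ms] == seq_len(n)
  sum(mutual) / n
}

#' Most-similar-node table
#'
#' One row per node with its most similar node (external labels), using the
#' same tie-break as [mutual_most_similar_ratio()]. When a single node is the
#' most similar node of more than half of all nodes — the "general similar
#' node" pathology that afflicts degree-driven indices on hub-heavy graphs —
#' its label is recorded in the `general_similar` attribute.
#'
#' @param sim a `similarity_matrix`.
#' @return data frame with columns `node`, `most_similar`; attribute
#'   `general_similar` (character vector, possibly empty).
#' @export
most_similar_pairs <- function(sim) {
  labs <- rownames(sim)
  ms <- most_similar_vector(sim)
  out <- data.frame(node = labs, most_similar = labs[ms], stringsAsFactors = FALSE)
  counts <- table(factor(ms, levels = seq_along(labs)))
  attr(out, "general_similar") <- labs[counts > length(labs) / 2]
  out
}

#' Write the most-similar-node table as TSV
#'
#' @param sim a `similarity_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_most_similar_tsv <- function(sim, path) {
  mp <- most_similar_pairs(sim)
  writeLines(c("node\tmost_similar",
               sprintf("%s\t%s", mp$node, mp$most_similar)), path)
  invisible(path)
}

#' Link-prediction AUC
#'
#' `auc_sampled()` is the sampled estimator: `r` independent draws (with
#' replacement) of one probe edge and one unknown pair; with `r1` draws where
#' the probe edge scores strictly higher and `r2` draws with equal scores,
#' `AUC = (r1 + r2 / 2) / r`. `auc_exact()` enumerates every
#' (probe, unknown) pair and is the exact expectation of the sampled
#' estimator — useful as a deterministic oracle.
#'
#' The similarity matrix must be computed from the training graph of the same
#' split, never from the full graph.
#'
#' @param sim a `similarity_matrix` computed on `split$train_graph`.
#' @param split a `link_split` from [split_edges()].
#' @param r number of sampled comparisons; default 10,000.
#' @param seed integer seed for the draws.
#' @return a number in `[0, 1]`.
#' @export
auc_sampled <- function(sim, split, r = 10000, seed) {
  if (r < 1) stop("r must be >= 1")
  sp <- probe_scores(sim, split)
  su <- unknown_scores(sim, split)
  set.seed(seed)
  ip <- sample.int(length(sp), r, replace = TRUE)
  iu <- sample.int(length(su), r, replace = TRUE)
  a <- sp[ip]; b <- su[iu]
  (sum(a > b) + sum(a == b) / 2) / r
}

#' @rdname auc_sampled
#' @export
auc_exact <- function(sim, split) {
  sp <- probe_scores(sim, split)
  su <- unknown_scores(sim, split)
  # rank-based count of (probe > unknown) pairs plus half the ties
  combined <- c(sp, su)
  rk <- rank(combined)                     # midranks handle ties
  sum_rk_probe <- sum(rk[seq_along(sp)])
  wins <- sum_rk_probe - length(sp) * (length(sp) + 1) / 2
  wins / (length(sp) * length(su))
}

probe_scores <- function(sim, split) {
  if (nrow(split$probe) == 0) stop("empty probe set")
  unclass_sim(sim)[cbind(split$probe$i, split$probe$j)]
}

unknown_scores <- function(sim, split) {
  if (nrow(split$unknown) == 0) stop("empty unknown-edge set")
  unclass_sim(sim)[cbind(split$unknown$i, split$unknown$j)]
}

#' Run a full evaluation experiment
#'
#' For `metric = "auc"`: each replicate draws a fresh train/probe split
#' (seed = `base_seed` + replicate index), computes the chosen index on the
#' training graph only, and scores it with [auc_sampled()] (same per-replicate
#' seed); the reported value is the mean over replicates. For
#' `metric = "ms"`: the index is computed once on the full observed graph and
#' [mutual_most_similar_ratio()] is returned (no randomness, so a single
#' replicate).
#'
#' @param g a `weighted_graph`.
#' @param index index name, see [similarity_index()].
#' @param metric `"auc"` or `"ms"`.
#' @param d,t index parameters, see [similarity_index()].
#' @param train_fraction training proportion for AUC splits; default 0.9.
#' @param replicates number of independent splits for AUC; default 30.
#' @param r sampled comparisons per replicate; default 10,000.
#' @param base_seed integer; replicate `i` uses seed `base_seed + i`.
#' @return an object of class `evaluation_result`: list with `metric`,
#'   `index`, `d`, `value` (mean), `per_replicate`, `replicates`, `seeds`.
#' @export
run_experiment <- function(g, index, metric = c("auc", "ms"), d = 5, t = 3,
                           train_fraction = 0.9, replicates = 30, r = 10000,
                           base_seed = 1) {
  metric <- match.arg(metric)
  if (replicates < 1) stop("replicates must be >= 1")
  if (metric == "ms") {
    sim <- similarity_index(g, index, d = d, t = t)
    val <- mutual_most_similar_ratio(sim)
    res <- list(metric = "ms", index = index, d = d, value = val,
                per_replicate = val, replicates = 1L, seeds = integer(0))
  } else {
    seeds <- base_seed + seq_len(replicates)
    vals <- vapply(seeds, function(sd) {
      split <- split_edges(g, train_fraction, seed = sd)
      sim <- similarity_index(split$train_graph, index, d = d, t = t)
      auc_sampled(sim, split, r = r, seed = sd)
    }, numeric(1))
    res <- list(metric = "auc", index = index, d = d, value = mean(vals),
                per_replicate = vals, replicates = as.integer(replicates),
                seeds = seeds)
  }
  class(res) <- "evaluation_result"
  res
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("%s(%s, d = %d) = %.4f over %d replicate(s)\n",
              toupper(x$metric), x$index, x$d, x$value, x$replicates))
  invisible(x)
}
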