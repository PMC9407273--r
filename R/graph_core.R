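#' Construct a weighted graph from a weight matrix
#'
#' The central data structure of the package: an undirected simple graph with
#' positive edge weights, stored as a dense symmetric weight matrix with zero
#' diagonal. An edge exists between nodes `x` and `y` exactly when
#' `w[x, y] > 0`; the adjacency indicator, node degrees `k_x` (number of
#' incident edges) and node strengths `s_x` (sum of incident weights) are all
#' derived from the matrix.
#'
#' @param w square numeric matrix of edge weights; must be symmetric,
#'   nonnegative, with zero diagonal.
#' @param labels optional character vector of external node labels. Defaults
#'   to `"v1"`, `"v2"`, ... External labels are preserved on output; all
#'   internal computation uses dense 1-based indices.
#' @return An object of class `weighted_graph`: a list with elements
#'   `labels` (character) and `w` (numeric matrix, dimnames set to labels).
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 3.5
#' w[2, 3] <- w[3, 2] <- 1
#' g <- weighted_graph(w)
#' n_edges(g)
#' strengths(g)
#' @export
weighted_graph <- function(w, labels = NULL) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) {
    stop("weight matrix must be square, got ", nrow(w), " x ", ncol(w))
  }
  if (!is.numeric(w)) stop("weight matrix must be numeric")
  n <- nrow(w)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(w))) rownames(w) else paste0("v", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) stop("need one label per node")
  if (anyDuplicated(labels)) stop("node labels must be unique")
  if (any(is.na(w))) stop("weight matrix contains NA")
  if (any(w < 0)) stop("edge weights must be nonnegative")
  if (!isTRUE(all.equal(w, t(w), tolerance = 0, check.attributes = FALSE))) {
    stop("weight matrix must be symmetric")
  }
  if (any(diag(w) != 0)) stop("weight matrix must have a zero diagonal (no self-loops)")
  dimnames(w) <- list(labels, labels)
  structure(list(labels = labels, w = w), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted_graph: %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Basic weighted-graph accessors
#'
#' `n_nodes()` and `n_edges()` count nodes and (undirected) edges;
#' `degrees()` returns `k_x`, the number of edges incident to each node;
#' `strengths()` returns `s_x`, the sum of weights on edges incident to each
#' node; `adjacency()` returns the 0/1 adjacency indicator matrix;
#' `weight_matrix()` the symmetric weight matrix.
#'
#' @param g a `weighted_graph`.
#' @return Integer or numeric scalar/vector/matrix as described; vectors are
#'   named by the external node labels.
#' @export
n_nodes <- function(g) length(g$labels)

#' @rdname n_nodes
#' @export
n_edges <- function(g) sum(g$w[upper.tri(g$w)] > 0)

#' @rdname n_nodes
#' @export
degrees <- function(g) {
  k <- rowSums(g$w > 0)
  names(k) <- g$labels
  k
}

#' @rdname n_nodes
#' @export
strengths <- function(g) {
  s <- rowSums(g$w)
  names(s) <- g$labels
  s
}

#' @rdname n_nodes
#' @export
adjacency <- function(g) (g$w > 0) + 0

#' @rdname n_nodes
#' @export
weight_matrix <- function(g) g$w

#' Edge table of a weighted graph
#'
#' Lists every undirected edge once, as a data frame of internal indices,
#' external labels and weights, in canonical (column-major upper-triangle)
#' order. This ordering is relied on wherever edges are sampled or weights
#' are assigned, so results are reproducible for a given seed.
#'
#' @param g a `weighted_graph`.
#' @return data frame with columns `i`, `j` (integer indices, `i < j`),
#'   `u`, `v` (labels) and `w` (weight).
#' @export
edge_table <- function(g) {
  idx <- which(upper.tri(g$w) & g$w > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  data.frame(
    i = idx[, 1], j = idx[, 2],
    u = g$labels[idx[, 1]], v = g$labels[idx[, 2]],
    w = g$w[idx],
    stringsAsFactors = FALSE
  )
}

## build a weighted_graph from parallel vectors of endpoint labels + weights;
## duplicate unordered pairs keep the last weight seen, self-loops are dropped
## with a warning (mirrors the preprocessing applied to the benchmark datasets)
graph_from_edge_vectors <- function(u, v, w, labels = NULL) {
  u <- as.character(u)
  v <- as.character(v)
  self <- u == v
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    u <- u[!self]; v <- v[!self]; w <- w[!self]
  }
  if (is.null(labels)) {
    labels <- unique(c(rbind(u, v)))
  } else {
    labels <- as.character(labels)
    missing <- setdiff(c(u, v), labels)
    if (length(missing) > 0) {
      stop("edge endpoint(s) not in vertex list: ", paste(missing, collapse = ", "))
    }
  }
  n <- length(labels)
  wm <- matrix(0, n, n)
  iu <- match(u, labels)
  iv <- match(v, labels)
  for (e in seq_along(iu)) {          # sequential so "keep last" wins on duplicates
    wm[iu[e], iv[e]] <- w[e]
    wm[iv[e], iu[e]] <- w[e]
  }
  weighted_graph(wm, labels)
}

#' Read a weighted edge list
#'
#' Parses whitespace-separated `u v w` lines into a [weighted_graph()]. Lines
#' may carry two tokens (the edge gets `default_weight`) or three. Comment
#' lines and blank lines are skipped. Duplicate lines for the same unordered
#' pair collapse to a single edge keeping the last weight seen; self-loops are
#' dropped with a warning.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @param comment_prefix lines starting with this prefix are ignored.
#' @param default_weight weight given to 2-token lines; with the default 1 the
#'   graph degenerates to its unweighted form.
#' @return a `weighted_graph`; node labels appear in order of first mention.
#' @examples
#' g <- read_weighted_edge_list(text = c("1 2 3.5", "2 3 1.0"))
#' n_edges(g)
#' @export
read_weighted_edge_list <- function(path = NULL, text = NULL,
                                    comment_prefix = "#", default_weight = 1) {
  if (default_weight <= 0) stop("default_weight must be positive")
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  u <- character(0); v <- character(0); w <- numeric(0)
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (raw == "" || startsWith(raw, comment_prefix)) next
    toks <- strsplit(raw, "[[:space:]]+")[[1]]
    if (length(toks) < 2 || length(toks) > 3) {
      stop("line ", ln, ": expected 2 or 3 whitespace-separated tokens, got ",
           length(toks))
    }
    wt <- if (length(toks) == 3) suppressWarnings(as.numeric(toks[[3]])) else default_weight
    if (is.na(wt)) stop("line ", ln, ": weight '", toks[[3]], "' is not a number")
    if (wt <= 0) stop("line ", ln, ": edge weight must be positive, got ", wt)
    u <- c(u, toks[[1]]); v <- c(v, toks[[2]]); w <- c(w, wt)
  }
  if (length(u) == 0) stop("no edges found in input")
  graph_from_edge_vectors(u, v, w)
}

#' Write a weighted edge list
#'
#' Inverse of [read_weighted_edge_list()]: one `u v w` line per edge, weights
#' serialised at full double precision so that a read-back reproduces the
#' weight matrix bit-exactly.
#'
#' @param g a `weighted_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weighted_edge_list <- function(g, path) {
  et <- edge_table(g)
  lines <- sprintf("%s %s %.17g", et$u, et$v, et$w)
  writeLines(lines, path)
  invisible(path)
}

#' Read a Pajek .net file
#'
#' Reads the subset of the Pajek format used to distribute weighted networks
#' (e.g. air-transport data): a `*Vertices N` section with optional quoted
#' labels, followed by one or more `*Edges` / `*Arcs` sections of
#' `u v [w]` lines (1-based vertex indices). Arcs are symmetrised into
#' undirected edges; duplicate pairs keep the last weight seen.
#'
#' @param path file path, or lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @param default_weight weight for edge lines without a weight token.
#' @return a `weighted_graph` with labels from the vertices section.
#' @export
read_pajek <- function(path = NULL, text = NULL, default_weight = 1) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  hdr <- grep("^\\*[Vv]ertices", lines)
  if (length(hdr) == 0) stop("not a Pajek file: missing *Vertices header")
  hdr <- hdr[[1]]
  nv <- suppressWarnings(as.integer(strsplit(lines[[hdr]], "[[:space:]]+")[[1]][[2]]))
  if (is.na(nv) || nv < 1) stop("invalid vertex count in *Vertices header")
  labels <- paste0("v", seq_len(nv))
  sec <- grep("^\\*", lines)
  body_end <- if (any(sec > hdr)) min(sec[sec > hdr]) - 1 else length(lines)
  if (body_end > hdr) {
    for (ln in lines[(hdr + 1):body_end]) {
      m <- regmatches(ln, regexec('^([0-9]+)[[:space:]]+"([^"]*)"', ln))[[1]]
      if (length(m) == 3) {
        id <- as.integer(m[[2]])
        if (id >= 1 && id <= nv) labels[[id]] <- m[[3]]
      }
    }
  }
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  edge_hdrs <- grep("^\\*([Ee]dges|[Aa]rcs)", lines)
  if (length(edge_hdrs) == 0) stop("not a Pajek file: missing *Edges/*Arcs section")
  iu <- integer(0); iv <- integer(0); w <- numeric(0)
  for (h in edge_hdrs) {
    nxt <- sec[sec > h]
    to <- if (length(nxt)) min(nxt) - 1 else length(lines)
    if (to < h + 1) next
    for (ln in lines[(h + 1):to]) {
      toks <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(toks) < 2) stop("malformed Pajek edge line: '", ln, "'")
      a <- suppressWarnings(as.integer(toks[[1]]))
      b <- suppressWarnings(as.integer(toks[[2]]))
      if (is.na(a) || is.na(b)) stop("malformed Pajek edge line: '", ln, "'")
      if (a < 1 || a > nv || b < 1 || b > nv) {
        stop("vertex index out of range in edge line: '", ln, "' (n = ", nv, ")")
      }
      wt <- if (length(toks) >= 3) suppressWarnings(as.numeric(toks[[3]])) else default_weight
      if (is.na(wt)) stop("malformed weight in Pajek edge line: '", ln, "'")
      if (wt <= 0) stop("edge weight must be positive in line: '", ln, "'")
      iu <- c(iu, a); iv <- c(iv, b); w <- c(w, wt)
    }
  }
  if (length(iu) == 0) stop("Pajek file contains no edges")
  graph_from_edge_vectors(labels[iu], labels[iv], w, labels = labels)
}

#' Write a Pajek .net file
#'
#' @param g a `weighted_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pajek <- function(g, path) {
  n <- n_nodes(g)
  et <- edge_table(g)
  lines <- c(
    sprintf("*Vertices %d", n),
    sprintf('%d "%s"', seq_len(n), g$labels),
    "*Edges",
    sprintf("%d %d %.17g", et$i, et$j, et$w)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted adjacency matrix from CSV
#'
#' Accepts a square numeric matrix, optionally preceded by a header row of
#' node labels. The header is detected by attempting to parse the first row
#' as numbers.
#'
#' @param path file path.
#' @return a `weighted_graph`.
#' @export
read_adjacency_csv <- function(path) {
  first <- strsplit(readLines(path, n = 1L), ",")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  m <- as.matrix(utils::read.csv(path, header = has_header, check.names = FALSE))
  labels <- if (has_header) colnames(m) else NULL
  storage.mode(m) <- "double"
  weighted_graph(m, labels = labels)
}

## local clustering coefficients via igraph; nodes with k < 2 contribute 0
local_clustering <- function(g, weighted_variant = c("none", "barrat", "onnela")) {
  weighted_variant <- match.arg(weighted_variant)
  if (weighted_variant == "onnela") {
    # Onnela et al.: geometric mean of weights normalised by max weight
    w <- g$w
    wmax <- max(w)
    if (wmax == 0) return(rep(0, n_nodes(g)))
    wh <- (w / wmax)^(1 / 3)
    num <- diag(wh %*% wh %*% wh)
    k <- rowSums(w > 0)
    denom <- k * (k - 1)
    cc <- ifelse(denom > 0, num / denom, 0)
    return(as.numeric(cc))
  }
  ig <- igraph::graph_from_adjacency_matrix(g$w, mode = "undirected", weighted = TRUE)
  type <- if (weighted_variant == "barrat") "barrat" else "local"
  weights <- if (weighted_variant == "barrat") igraph::E(ig)$weight else NA
  cc <- igraph::transitivity(ig, type = type, weights = weights, isolates = "zero")
  cc[is.na(cc)] <- 0
  cc
}

#' Topology summary statistics of a weighted graph
#'
#' The seven headline statistics used to characterise weighted networks:
#' node count `n`, edge count `m`, mean degree, mean strength, mean (binary)
#' local clustering coefficient, mean weighted clustering coefficient and
#' density `rho = 2m / (n (n - 1))`. Nodes of degree below 2 contribute 0 to
#' the clustering means.
#'
#' The field has no single weighted clustering coefficient; `"barrat"`
#' (default, weight share of wedges closed by a triangle) and `"onnela"`
#' (geometric mean of max-normalised triangle weights) are both offered.
#'
#' @param g a `weighted_graph` with at least 2 nodes.
#' @param weighted_cc_variant `"barrat"` or `"onnela"`.
#' @return an object of class `topology_stats` (a named list).
#' @export
topology_stats <- function(g, weighted_cc_variant = c("barrat", "onnela")) {
  weighted_cc_variant <- match.arg(weighted_cc_variant)
  n <- n_nodes(g)
  if (n < 2) stop("topology statistics need at least 2 nodes")
  m <- n_edges(g)
  out <- list(
    n = n,
    m = m,
    mean_degree = mean(degrees(g)),
    mean_strength = mean(strengths(g)),
    mean_clustering = mean(local_clustering(g, "none")),
    mean_weighted_clustering = mean(local_clustering(g, weighted_cc_variant)),
    density = 2 * m / (n * (n - 1)),
    weighted_cc_variant = weighted_cc_variant
  )
  class(out) <- "topology_stats"
  out
}

#' @export
print.topology_stats <- function(x, ...) {
  cat(sprintf(
    paste0("n = %d, m = %d, <k> = %.4f, <s> = %.4f, <c> = %.4f, ",
           "<c_w> = %.4f (%s), rho = %.4f\n"),
    x$n, x$m, x$mean_degree, x$mean_strength, x$mean_clustering,
    x$mean_weighted_clustering, x$weighted_cc_variant, x$density
  ))
  invisible(x)
}

#' @export
as.data.frame.topology_stats <- function(x, ...) {
  data.frame(
    n = x$n, m = x$m, mean_degree = x$mean_degree,
    mean_strength = x$mean_strength, mean_clustering = x$mean_clustering,
    mean_weighted_clustering = x$mean_weighted_clustering,
    density = x$density, stringsAsFactors = FALSE
  )
}
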