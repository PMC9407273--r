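#' Structural weights of nodes
#'
#' Three scalar summaries combine a node's degree `k_x` (its capacity to
#' diffuse information) and strength `s_x` (its capacity to collect it):
#'
#' * unit weight `uw(x) = s_x / k_x` — the mean weight of its incident edges;
#' * degree weight `dw(x) = k_x^2 / sum(k) * 1 / s_x` — degree-dominant,
#'   strength-suppressed;
#' * strength weight `sw(x) = s_x^2 / sum(s) * 1 / k_x` — strength-dominant,
#'   degree-suppressed.
#'
#' The sums run over all nodes, including `x` itself. On an all-unit-weight
#' graph these degenerate to `uw = 1` and `dw = sw = k_x / (2m)`.
#' Isolated nodes (`k_x = 0`) receive the conventional value 0 for all three
#' weights and are excluded from top-d rankings.
#'
#' @param g a `weighted_graph`.
#' @param node internal node index (1-based).
#' @return `unit_weight()`, `degree_weight()` and `strength_weight()` return a
#'   single numeric value; `structural_weight_set()` returns an `n x 3` numeric
#'   matrix with columns `uw`, `dw`, `sw` and row names the external labels.
#' @examples
#' g <- read_weighted_edge_list(text = c("a b 2", "a c 4"))
#' unit_weight(g, 1)  # node "a": mean of 2 and 4
#' structural_weight_set(g)
#' @export
structural_weight_set <- function(g) {
  k <- as.numeric(degrees(g))
  s <- as.numeric(strengths(g))
  sum_k <- sum(k)
  sum_s <- sum(s)
  uw <- ifelse(k > 0, s / k, 0)
  dw <- ifelse(k > 0, k^2 / sum_k / s, 0)
  sw <- ifelse(k > 0, s^2 / sum_s / k, 0)
  out <- cbind(uw = uw, dw = dw, sw = sw)
  rownames(out) <- g$labels
  out
}

#' @rdname structural_weight_set
#' @export
unit_weight <- function(g, node) {
  k <- sum(g$w[node, ] > 0)
  if (k == 0) return(0)
  sum(g$w[node, ]) / k
}

#' @rdname structural_weight_set
#' @export
degree_weight <- function(g, node) {
  k <- sum(g$w[node, ] > 0)
  if (k == 0) return(0)
  s <- sum(g$w[node, ])
  k^2 / sum(degrees(g)) / s
}

#' @rdname structural_weight_set
#' @export
strength_weight <- function(g, node) {
  k <- sum(g$w[node, ] > 0)
  if (k == 0) return(0)
  s <- sum(g$w[node, ])
  s^2 / sum(strengths(g)) / k
}

#' Export structural weights as CSV
#'
#' Writes one row per node: `label,uw,dw,sw`.
#'
#' @param g a `weighted_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structural_weights_csv <- function(g, path) {
  sa <- structural_weight_set(g)
  df <- data.frame(label = rownames(sa), uw = sa[, "uw"], dw = sa[, "dw"],
                   sw = sa[, "sw"], stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
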