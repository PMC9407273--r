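#' Similarity matrix objects
#'
#' All indices in the package return a symmetric `n x n` numeric matrix of
#' class `similarity_matrix`, with dimnames set to the external node labels
#' and an `index` attribute naming the producing index. Diagonal conventions
#' differ by family and are never consulted by the evaluation protocols:
#' the common-neighbour family (cn, wcn, aa, waa) and lrw use diagonal 0,
#' the relative-entropy family (redd, re-lrw, lre) diagonal 1.
#'
#' @param scores symmetric numeric matrix.
#' @param index name of the producing index.
#' @param labels node labels (defaults to existing dimnames).
#' @return a `similarity_matrix`.
#' @export
similarity_matrix <- function(scores, index, labels = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores)) stop("similarity matrix must be square")
  if (max(abs(scores - t(scores))) > 1e-9) stop("similarity matrix must be symmetric")
  if (is.null(labels)) labels <- rownames(scores)
  if (is.null(labels)) labels <- paste0("v", seq_len(nrow(scores)))
  dimnames(scores) <- list(labels, labels)
  structure(scores, class = c("similarity_matrix", "matrix", "array"),
            index = index)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s): %d x %d\n",
              attr(x, "index"), nrow(x), ncol(x)))
  print(unclass_sim(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

## strip class/attrs for plain-matrix arithmetic
unclass_sim <- function(x) {
  attr(x, "index") <- NULL
  class(x) <- NULL
  x
}

#' Write a similarity matrix to CSV / long TSV
#'
#' `write_similarity_csv()` writes the full square matrix with labels as
#' header row and first column. `write_similarity_long_tsv()` writes one
#' `u v score` line per unordered node pair (upper triangle).
#'
#' @param sim a `similarity_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(sim, path) {
  utils::write.csv(unclass_sim(sim), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_similarity_csv
#' @export
write_similarity_long_tsv <- function(sim, path) {
  labs <- rownames(sim)
  ut <- which(upper.tri(sim), arr.ind = TRUE)
  lines <- sprintf("%s\t%s\t%.17g", labs[ut[, 1]], labs[ut[, 2]], sim[ut])
  writeLines(c("u\tv\tscore", lines), path)
  invisible(path)
}
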