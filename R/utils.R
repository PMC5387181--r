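# Internal helpers for undirected-edge bookkeeping.
#
# All edge vectors follow the column-major upper-triangle order of
# `m[upper.tri(m)]`, so a matrix and its flattened edge vector can be
# converted back and forth without an explicit index table.

#' Number of possible edges in an undirected simple graph
#'
#' @param n_nodes Number of nodes.
#' @return Integer count `n (n - 1) / 2`.
#' @export
#' @examples
#' n_possible_edges(91)
n_possible_edges <- function(n_nodes) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1, n_nodes >= 1)
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

# tibble of unordered node pairs (i < j) in upper.tri order
edge_pairs <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  j <- rep(2:n_nodes, times = seq_len(n_nodes - 1))
  i <- unlist(lapply(2:n_nodes, function(jj) seq_len(jj - 1)), use.names = FALSE)
  tibble::tibble(i = i, j = j)
}

# flatten the upper triangle of a symmetric matrix to an edge vector
ut_values <- function(m) m[upper.tri(m)]

# rebuild a symmetric matrix (zero diagonal) from an edge vector
sym_from_ut <- function(values, n_nodes, diag_value = 0) {
  m <- matrix(0, n_nodes, n_nodes)
  m[upper.tri(m)] <- values
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

# round-half-up; used for the retained-edge count k = round(d * M) so the
# achieved density stays within 1/M of the target symmetrically
round_half_up <- function(x) floor(x + 0.5)

# deterministic edge ranking used by every count-based threshold:
# streamline count descending, ties broken by higher NDI, then by (i, j).
# Returns a permutation of seq_along(counts).
rank_edges_by_count <- function(counts, ndi, pairs) {
  ndi[is.na(ndi)] <- -Inf
  order(-counts, -ndi, pairs$i, pairs$j)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# default region labels for the synthetic parcellation
default_node_labels <- function(n_nodes) sprintf("R%03d", seq_len(n_nodes))

`%||%` <- function(a, b) if (is.null(a)) b else a
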