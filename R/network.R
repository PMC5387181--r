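#' Weighted network
#'
#' One symmetric weighted graph derived from a connectome, tagged with the
#' weight kind: `FS` (fraction of streamlines), `FA`, `NDI`, `ODI_C`
#' (coherence, 1-ODI) or `BINARY`. Carries the streamline counts used for
#' thresholding decisions.
#'
#' @param weights Symmetric non-negative matrix, zero diagonal.
#' @param weight_kind One of `"FS", "FA", "NDI", "ODI_C", "BINARY"`.
#' @param counts Symmetric count matrix backing the edges (same sparsity).
#' @param node_labels Region names.
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, weight_kind, counts = NULL,
                             node_labels = NULL) {
  weight_kind <- match.arg(weight_kind, c("FS", "FA", "NDI", "ODI_C", "BINARY"))
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (any(abs(weights - t(weights)) > 1e-9)) {
    stop("weights must be symmetric", call. = FALSE)
  }
  if (any(diag(weights) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  structure(
    list(weights = weights, weight_kind = weight_kind,
         counts = counts, node_labels = node_labels %||% default_node_labels(n)),
    class = "weighted_network"
  )
}

n_nodes <- function(net) nrow(net$weights)
n_edges <- function(net) sum(ut_values(net$weights) > 0)

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network:%s> %d nodes, %d edges (density %.3f)%s\n",
              x$weight_kind, n_nodes(x), n_edges(x),
              network_density(x),
              if (isTRUE(attr(x, "empty"))) " [empty after filtering]" else ""))
  invisible(x)
}

#' Build a raw weighted network from a connectome
#'
#' Applies the streamline filter (edges with fewer than `min_streamlines`
#' streamlines are removed; default 5) and attaches the requested edge weight:
#'
#' * `FS`: streamline count divided by the total count over all surviving
#'   unordered edges, so surviving FS weights sum to 1;
#' * `FA`, `NDI`: the stored per-edge medians;
#' * `ODI_C`: coherence, `1 - ODI`;
#' * `BINARY`: 1 on every surviving edge.
#'
#' @param connectome A [multiweight_connectome()].
#' @param weight_kind `"FS"`, `"FA"`, `"NDI"`, `"ODI_C"` or `"BINARY"`.
#' @param min_streamlines Minimum streamline count for an edge to survive.
#' @return A [weighted_network()]. If no edge survives, the result has zero
#'   edges and attribute `empty = TRUE`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 1, n_repeat_scans = 0,
#'                                         node_count = 15, seed = 3))
#' build_network(cohort$connectome[[1]], "FS")
build_network <- function(connectome, weight_kind = c("FS", "FA", "NDI",
                                                      "ODI_C", "BINARY"),
                          min_streamlines = 5) {
  weight_kind <- match.arg(weight_kind)
  stopifnot(min_streamlines >= 1)
  n <- nrow(connectome$counts)
  cnt <- ut_values(connectome$counts)
  keep <- cnt >= min_streamlines

  w <- numeric(length(cnt))
  if (any(keep)) {
    w[keep] <- switch(
      weight_kind,
      FS = cnt[keep] / sum(cnt[keep]),
      FA = ut_values(connectome$fa)[keep],
      NDI = ut_values(connectome$ndi)[keep],
      ODI_C = 1 - ut_values(connectome$odi)[keep],
      BINARY = 1
    )
  }
  cnt_kept <- ifelse(keep, cnt, 0L)
  net <- weighted_network(sym_from_ut(w, n), weight_kind,
                          counts = sym_from_ut(cnt_kept, n),
                          node_labels = connectome$node_labels)
  if (!any(keep)) attr(net, "empty") <- TRUE
  net
}

#' Median connectivity of a network
#'
#' The median weight over existing (non-zero) edges. For an even number of
#' edges the usual mid-pair mean is taken.
#'
#' @param net A [weighted_network()].
#' @return A single number.
#' @export
median_connectivity <- function(net) {
  w <- ut_values(net$weights)
  w <- w[w > 0]
  if (length(w) == 0) {
    stop("median connectivity undefined: network has no edges", call. = FALSE)
  }
  stats::median(w)
}

# igraph view of a weighted network (existing edges only, weight attribute)
as_igraph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}
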