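#' Multi-weight connectome
#'
#' A single scan's structural connectome on a fixed parcellation: a symmetric
#' matrix of streamline counts plus per-edge median microstructure (FA, NDI,
#' ODI). Microstructure is defined only on edges with at least one streamline;
#' entries for absent edges are `NA`. ODI is stored as dispersion; the
#' coherence weight 1-ODI is computed when networks are built.
#'
#' @param counts Symmetric non-negative integer matrix with zero diagonal;
#'   `counts[i, j]` is the number of filtered streamlines linking regions
#'   `i` and `j`.
#' @param fa,ndi,odi Symmetric matrices of per-edge median microstructure in
#'   `[0, 1]`, `NA` where `counts == 0`.
#' @param node_labels Character vector of region names, one per node.
#' @return An object of class `multiweight_connectome`.
#' @export
multiweight_connectome <- function(counts, fa, ndi, odi, node_labels = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  node_labels <- node_labels %||% default_node_labels(n)
  x <- structure(
    list(counts = counts, fa = as.matrix(fa), ndi = as.matrix(ndi),
         odi = as.matrix(odi), node_labels = as.character(node_labels)),
    class = "multiweight_connectome"
  )
  validate_connectome(x)
}

validate_connectome <- function(x, what = "connectome") {
  n <- nrow(x$counts)
  if (ncol(x$counts) != n || n < 2) {
    stop(what, ": counts must be a square matrix with >= 2 nodes", call. = FALSE)
  }
  if (length(x$node_labels) != n) {
    stop(what, ": node_labels length must equal node count", call. = FALSE)
  }
  bad <- which(abs(x$counts - t(x$counts)) > 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("%s: counts asymmetric at edge (%d,%d)", what,
                 min(bad[1, ]), max(bad[1, ])), call. = FALSE)
  }
  if (any(diag(x$counts) != 0)) {
    stop(what, ": self-connections must be zero", call. = FALSE)
  }
  if (any(x$counts < 0) || any(x$counts != round(x$counts))) {
    stop(what, ": counts must be non-negative integers", call. = FALSE)
  }
  for (nm in c("fa", "ndi", "odi")) {
    m <- x[[nm]]
    if (!all(dim(m) == c(n, n))) {
      stop(what, ": ", nm, " must match counts dimensions", call. = FALSE)
    }
    v <- m[x$counts > 0]
    if (anyNA(v)) {
      stop(what, ": ", nm, " undefined on an edge with counts > 0", call. = FALSE)
    }
    if (any(v < 0 | v > 1)) {
      stop(what, ": ", nm, " values must lie in [0, 1]", call. = FALSE)
    }
    dv <- abs(m - t(m))
    if (any(dv[!is.na(dv)] > 1e-9)) {
      stop(what, ": ", nm, " asymmetric", call. = FALSE)
    }
  }
  x
}

#' @export
print.multiweight_connectome <- function(x, ...) {
  n <- nrow(x$counts)
  ne <- sum(ut_values(x$counts) > 0)
  cat(sprintf("<multiweight_connectome> %d nodes, %d/%d edges (density %.3f)\n",
              n, ne, n_possible_edges(n), ne / n_possible_edges(n)))
  invisible(x)
}

#' Connectome as a long edge table
#'
#' Tidy view of a connectome: one row per unordered region pair with at least
#' one streamline, `i < j`, 1-based indices.
#'
#' @param connectome A [multiweight_connectome()].
#' @param keep_absent Include zero-count pairs as rows (with `NA`
#'   microstructure)? Default `FALSE`.
#' @return A tibble with columns `i, j, region_i, region_j, count, fa, ndi, odi`.
#' @export
connectome_edges <- function(connectome, keep_absent = FALSE) {
  n <- nrow(connectome$counts)
  pairs <- edge_pairs(n)
  tab <- tibble::tibble(
    i = pairs$i, j = pairs$j,
    region_i = connectome$node_labels[pairs$i],
    region_j = connectome$node_labels[pairs$j],
    count = ut_values(connectome$counts),
    fa = ut_values(connectome$fa),
    ndi = ut_values(connectome$ndi),
    odi = ut_values(connectome$odi)
  )
  if (!keep_absent) tab <- dplyr::filter(tab, .data$count > 0)
  tab
}

#' Rebuild a connectome from a long edge table
#'
#' Inverse of [connectome_edges()]: absent pairs get zero counts and `NA`
#' microstructure.
#'
#' @param edges Tibble with columns `i, j, count, fa, ndi, odi`.
#' @param n_nodes Number of nodes in the parcellation.
#' @param node_labels Optional region names.
#' @return A [multiweight_connectome()].
#' @export
connectome_from_edges <- function(edges, n_nodes, node_labels = NULL) {
  stopifnot(all(c("i", "j", "count", "fa", "ndi", "odi") %in% names(edges)))
  if (any(edges$i >= edges$j)) {
    stop("edge table must have i < j on every row", call. = FALSE)
  }
  mk <- function(col, empty) {
    m <- matrix(empty, n_nodes, n_nodes)
    m[cbind(edges$i, edges$j)] <- edges[[col]]
    m[cbind(edges$j, edges$i)] <- edges[[col]]
    if (is.na(empty)) diag(m) <- NA else diag(m) <- 0
    m
  }
  multiweight_connectome(
    counts = mk("count", 0), fa = mk("fa", NA_real_),
    ndi = mk("ndi", NA_real_), odi = mk("odi", NA_real_),
    node_labels = node_labels
  )
}
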