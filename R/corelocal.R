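# Betweenness-based core/local edge decomposition.

#' Identify the core connections of a network
#'
#' Ranks edges by edge betweenness centrality (descending) and takes the
#' minimal prefix whose cumulative betweenness reaches `share` (default 50%)
#' of the total: these are the core connections; the remainder are local.
#' Edges tied in betweenness with the boundary edge are all included, and the
#' achieved share is reported (it may exceed the requested share); this avoids
#' arbitrary exclusion among indistinguishable edges.
#'
#' By default geodesics are computed with inverse streamline-count lengths
#' (the counts the network was thresholded by), since thresholds and edge
#' ranks are count-based; `betweenness_on` switches to the carried weights or
#' to unit lengths.
#'
#' @param net A [weighted_network()] with at least one edge.
#' @param share Fraction of total betweenness the core must account for.
#' @param betweenness_on `"counts"` (default), `"weights"` or `"binary"`:
#'   edge lengths used for geodesics.
#' @return An object of class `core_local_partition`: list with tibbles
#'   `core` and `local` (columns `i, j, betweenness`), the achieved
#'   `core_betweenness_share`, `share`, and `all_zero` flag (`TRUE` when
#'   total betweenness is zero and the partition is determined by the tie
#'   rule alone).
#' @export
identify_core <- function(net, share = 0.5,
                          betweenness_on = c("counts", "weights", "binary")) {
  betweenness_on <- match.arg(betweenness_on)
  stopifnot(share > 0, share < 1)
  if (n_edges(net) < 1) stop("network has no edges", call. = FALSE)

  bnet <- switch(
    betweenness_on,
    counts = {
      if (is.null(net$counts)) stop("network carries no counts", call. = FALSE)
      weighted_network(net$counts * (net$weights > 0), "FS",
                       node_labels = net$node_labels)
    },
    weights = net,
    binary = weighted_network((net$weights > 0) * 1, "BINARY",
                              node_labels = net$node_labels)
  )
  eb <- edge_betweenness_map(bnet)
  cnt <- if (!is.null(net$counts)) net$counts[cbind(eb$i, eb$j)] else rep(0, nrow(eb))
  ord <- order(-eb$betweenness, -cnt, eb$i, eb$j)
  eb <- eb[ord, ]
  total <- sum(eb$betweenness)
  all_zero <- total <= 0

  if (all_zero) {
    core_rows <- seq_len(nrow(eb))      # every edge tied at zero
    achieved <- NA_real_
  } else {
    cum <- cumsum(eb$betweenness)
    m <- which(cum >= share * total - 1e-12)[1]
    boundary <- eb$betweenness[m]
    tol <- 1e-12 * max(1, abs(boundary))
    # edges are sorted descending, so ties with the boundary edge form a
    # contiguous block; include the whole block
    core_rows <- seq_len(max(which(abs(eb$betweenness - boundary) <= tol)))
    achieved <- cum[max(core_rows)] / total
  }
  core <- eb[core_rows, ]
  local <- eb[setdiff(seq_len(nrow(eb)), core_rows), ]
  structure(list(core = tibble::as_tibble(core),
                 local = tibble::as_tibble(local),
                 core_betweenness_share = achieved,
                 share = share, all_zero = all_zero,
                 betweenness_on = betweenness_on),
            class = "core_local_partition")
}

#' @export
print.core_local_partition <- function(x, ...) {
  cat(sprintf(
    "<core_local_partition> %d core / %d local edges; achieved share %s (target %.2f)%s\n",
    nrow(x$core), nrow(x$local),
    if (is.na(x$core_betweenness_share)) "NA"
    else sprintf("%.3f", x$core_betweenness_share),
    x$share,
    if (x$all_zero) " [all betweenness zero: tie rule only]" else ""))
  invisible(x)
}

#' Median core and local weights of a partition
#'
#' Median connection weight over the core and local edge sets of a partition,
#' taken from any weighted network on the same nodes (absolute or normalised
#' weights). An empty side yields `NA` with `*_empty = TRUE`.
#'
#' @param partition A [identify_core()] result.
#' @param weight_net A [weighted_network()] supplying the weights.
#' @return A one-row tibble: `median_core, median_local, core_empty,
#'   local_empty`.
#' @export
core_local_medians <- function(partition, weight_net) {
  med <- function(edges) {
    if (nrow(edges) == 0) return(NA_real_)
    stats::median(weight_net$weights[cbind(edges$i, edges$j)])
  }
  tibble::tibble(
    median_core = med(partition$core),
    median_local = med(partition$local),
    core_empty = nrow(partition$core) == 0,
    local_empty = nrow(partition$local) == 0
  )
}

#' Cost-integrated core/local median weights over the density sweep
#'
#' For one connectome: at each grid density, threshold by counts, identify the
#' betweenness core, and record the median (optionally normalised) weight of
#' core and local connections; then cost-integrate each across the grid.
#'
#' @inheritParams cost_threshold
#' @param grid Density grid.
#' @param normalized Use weights normalised to unit total at each density?
#' @param share Core betweenness share.
#' @return A one-row tibble: `core_median_ci`, `local_median_ci` (the
#'   cost-integrated medians), plus the per-density tibble in attribute
#'   `sweep`.
#' @export
core_local_sweep <- function(connectome, weight_kind = "NDI",
                             grid = density_grid(), normalized = TRUE,
                             share = 0.5, min_streamlines = 5,
                             scan_id = "scan") {
  rows <- purrr::map_dfr(grid, function(d) {
    net <- cost_threshold(connectome, weight_kind, d, min_streamlines, scan_id)
    part <- identify_core(net, share)
    wnet <- if (normalized) normalize_weights(net) else net
    dplyr::mutate(core_local_medians(part, wnet), density = d, .before = 1)
  })
  out <- tibble::tibble(
    core_median_ci = cost_integrate(rows$median_core),
    local_median_ci = cost_integrate(rows$median_local)
  )
  attr(out, "sweep") <- rows
  out
}
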