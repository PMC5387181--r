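# Cost-correction: proportional thresholding of raw networks to a common
# density, weight normalisation at each density, and cost-integration of
# per-density metrics over the sweep grid.

#' Threshold a connectome to a target network density
#'
#' Retains the `k = round(d * M)` edges with the highest streamline counts
#' (round-half-up; `M` possible edges), regardless of the weight kind carried
#' by the result — thresholding always ranks by counts. Ties in counts are
#' broken by higher NDI, then lexicographically by `(i, j)`, so the sweep is
#' deterministic and nested: the edge set at density `d` contains the edge set
#' at any lower density.
#'
#' @inheritParams build_network
#' @param d Target density in `(0, 1]`; must not exceed the raw (filtered)
#'   network density.
#' @param scan_id Optional label used in error messages.
#' @return A [weighted_network()] carrying the raw weights on retained edges.
#' @export
cost_threshold <- function(connectome, weight_kind = c("FS", "FA", "NDI",
                                                       "ODI_C", "BINARY"),
                           d, min_streamlines = 5, scan_id = "scan") {
  weight_kind <- match.arg(weight_kind)
  stopifnot(d > 0, d <= 1)
  raw <- build_network(connectome, weight_kind, min_streamlines)
  n <- n_nodes(raw)
  m <- n_possible_edges(n)
  raw_density <- network_density(raw)
  if (raw_density < d - 1e-12) {
    stop(sprintf(
      "%s: raw network density %.4f is below the requested density %.4f; the cost sweep is restricted to densities no greater than the sparsest raw network",
      scan_id, raw_density, d), call. = FALSE)
  }
  k <- round_half_up(d * m)
  pairs <- edge_pairs(n)
  cnt <- ut_values(raw$counts)
  ndi <- ut_values(connectome$ndi)
  ord <- rank_edges_by_count(cnt, ndi, pairs)
  ord <- ord[cnt[ord] > 0]          # only surviving raw edges are candidates
  keep_idx <- ord[seq_len(min(k, length(ord)))]

  w <- numeric(m)
  w[keep_idx] <- ut_values(raw$weights)[keep_idx]
  cnt_keep <- numeric(m)
  cnt_keep[keep_idx] <- cnt[keep_idx]
  weighted_network(sym_from_ut(w, n), weight_kind,
                   counts = sym_from_ut(cnt_keep, n),
                   node_labels = connectome$node_labels)
}

#' Normalise network weights to unit total
#'
#' Divides each retained weight by the sum of retained weights (unordered-edge
#' convention), producing a normalised weighted network whose upper-triangle
#' weights sum to 1. At a fixed density this removes total-strength
#' differences between subjects, leaving pure weighted topology.
#'
#' @param net A [weighted_network()] with at least one edge.
#' @return A [weighted_network()] with the same edges, weights summing to 1.
#' @export
normalize_weights <- function(net) {
  s <- total_strength(net)
  if (s == 0) {
    stop("cannot normalise: all weights are zero", call. = FALSE)
  }
  out <- net
  out$weights <- net$weights / s
  out
}

#' Cost-integrate a metric over a density sweep
#'
#' The arithmetic mean of a metric's per-density values over the sweep grid,
#' summarising the whole cost range in one number.
#'
#' @param values Numeric vector of per-density metric values (no missing
#'   values; partial sweeps are refused rather than silently averaged).
#' @return A single number.
#' @export
cost_integrate <- function(values) {
  if (length(values) == 0) stop("no density levels to integrate", call. = FALSE)
  if (anyNA(values)) {
    stop("missing metric values at ", sum(is.na(values)),
         " density level(s); cost integration requires the full sweep",
         call. = FALSE)
  }
  mean(values)
}

#' Default density grid
#'
#' Densities 0.05 to 0.50 in steps of 0.01 (46 levels). The upper bound
#' reflects the sparsest raw network the analysis admits.
#'
#' @param dmin,dmax,dstep Grid bounds and step.
#' @return Increasing numeric vector of densities.
#' @export
density_grid <- function(dmin = 0.05, dmax = 0.50, dstep = 0.01) {
  stopifnot(dmin > 0, dmax <= 1, dmax > dmin, dstep > 0)
  g <- seq(dmin, dmax, by = dstep)
  round(g, 10)
}

#' Density sweep of graph metrics for one connectome
#'
#' Thresholds the connectome at every grid density, optionally normalises the
#' retained weights to unit total, computes the requested metrics at each
#' level, and attaches their cost-integrated means.
#'
#' @inheritParams cost_threshold
#' @param grid Density grid, see [density_grid()].
#' @param metrics Metric names passed to [network_metrics()].
#' @param normalized Normalise weights at each density ([normalize_weights()])?
#' @return A tibble of class `neoconn_sweep` with columns `density, metric,
#'   value, weight_kind`; attribute `cost_integrated` holds a tibble of
#'   per-metric means.
#' @export
density_sweep <- function(connectome, weight_kind = "FS",
                          grid = density_grid(),
                          metrics = c("global_efficiency",
                                      "characteristic_path_length",
                                      "clustering_coefficient"),
                          normalized = FALSE, min_streamlines = 5,
                          scan_id = "scan") {
  stopifnot(all(diff(grid) > 0))
  rows <- purrr::map_dfr(grid, function(d) {
    net <- cost_threshold(connectome, weight_kind, d, min_streamlines, scan_id)
    if (normalized) net <- normalize_weights(net)
    dplyr::mutate(network_metrics(net, metrics), density = d, .before = 1)
  })
  ci <- rows |>
    dplyr::group_by(.data$metric, .data$weight_kind) |>
    dplyr::summarise(cost_integrated = cost_integrate(.data$value),
                     .groups = "drop")
  structure(rows, class = c("neoconn_sweep", class(rows)),
            cost_integrated = ci, normalized = normalized)
}
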