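# Weighted and binary graph-theory measures following the standard
# brain-connectivity-toolbox formulations. Geodesic lengths are the inverse of
# the connection weight (strong connections are short); this is isolated in
# weight_to_length() so alternatives such as -log(w) stay pluggable.

weight_to_length <- function(w, convention = c("inverse", "neglog")) {
  convention <- match.arg(convention)
  switch(convention, inverse = 1 / w, neglog = -log(w))
}

edge_lengths <- function(net, convention = "inverse") {
  g <- as_igraph(net)
  w <- igraph::E(g)$weight
  if (any(w < 0)) stop("negative weights are not allowed", call. = FALSE)
  if (net$weight_kind == "BINARY") {
    len <- rep(1, length(w))
  } else {
    len <- weight_to_length(w, convention)
  }
  list(graph = g, lengths = len)
}

#' Network density
#'
#' Existing connections as a fraction of all possible connections
#' `N (N - 1) / 2`.
#'
#' @param net A [weighted_network()].
#' @return A fraction in `[0, 1]`.
#' @export
network_density <- function(net) {
  stopifnot(n_nodes(net) >= 2)
  n_edges(net) / n_possible_edges(n_nodes(net))
}

#' Total network strength
#'
#' Sum of all connection weights (each unordered edge counted once).
#'
#' @param net A [weighted_network()].
#' @return A non-negative number.
#' @export
total_strength <- function(net) sum(ut_values(net$weights))

#' All-pairs geodesic distances
#'
#' Shortest-path distances with edge length equal to the inverse weight
#' (length 1 for binary networks); disconnected pairs get `Inf`.
#'
#' @param net A [weighted_network()].
#' @param convention Weight-to-length map, `"inverse"` (default) or
#'   `"neglog"`.
#' @return A symmetric numeric matrix of distances, zero diagonal.
#' @export
graph_distances <- function(net, convention = "inverse") {
  el <- edge_lengths(net, convention)
  d <- igraph::distances(el$graph, weights = el$lengths)
  dimnames(d) <- list(net$node_labels, net$node_labels)
  d
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse geodesic distance, with
#' `1/Inf = 0` for disconnected pairs. An integration measure, inversely
#' related to the characteristic path length.
#'
#' @inheritParams graph_distances
#' @return A number in `[0, max weight]` (in `[0, 1]` for binary networks).
#' @export
global_efficiency <- function(net, convention = "inverse") {
  stopifnot(n_nodes(net) >= 2)
  d <- graph_distances(net, convention)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n_nodes(net) * (n_nodes(net) - 1))
}

#' Local efficiency
#'
#' Average over nodes of the global efficiency of each node's neighbourhood
#' subgraph (the node's neighbours and the edges among them, with their
#' original weights). Nodes with fewer than two neighbours contribute zero.
#' A segregation measure, proportional to the clustering coefficient.
#'
#' @inheritParams graph_distances
#' @return A non-negative number.
#' @export
local_efficiency <- function(net, convention = "inverse") {
  n <- n_nodes(net)
  stopifnot(n >= 2)
  w <- net$weights
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(w[v, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- weighted_network(w[nb, nb, drop = FALSE], net$weight_kind,
                            node_labels = net$node_labels[nb])
    global_efficiency(sub, convention)
  }, numeric(1))
  mean(vals)
}

#' Characteristic path length
#'
#' Mean geodesic distance over connected ordered node pairs; infinite
#' distances from disconnected pairs are excluded (disconnection is captured
#' by [global_efficiency()] instead). `NA` if no pair is connected.
#'
#' @inheritParams graph_distances
#' @return A positive number, or `NA` for an edgeless network.
#' @export
characteristic_path_length <- function(net, convention = "inverse") {
  stopifnot(n_nodes(net) >= 2)
  d <- graph_distances(net, convention)
  off <- d[row(d) != col(d)]
  off <- off[is.finite(off)]
  if (length(off) == 0) return(NA_real_)
  mean(off)
}

#' Clustering coefficient
#'
#' Mean clustering over nodes. Binary networks use the triangle ratio
#' `2 t_i / (k_i (k_i - 1))`; weighted networks use the Onnela geometric-mean
#' form with weights rescaled by the maximum weight. Nodes with degree below
#' two contribute zero.
#'
#' @param net A [weighted_network()].
#' @return A number in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  n <- n_nodes(net)
  stopifnot(n >= 2)
  w <- net$weights
  if (max(w) == 0) return(0)
  wh <- if (net$weight_kind == "BINARY") (w > 0) * 1 else (w / max(w))^(1 / 3)
  if (net$weight_kind == "BINARY") wh <- wh  # 0/1 cube roots are themselves
  k <- rowSums(w > 0)
  tri <- diag(wh %*% wh %*% wh)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Edge betweenness centrality
#'
#' For each edge, the number of all-pairs shortest paths that use it, counted
#' fractionally when a node pair has several co-minimal geodesics. Geodesics
#' use inverse-weight lengths (unit lengths for binary networks).
#'
#' @inheritParams graph_distances
#' @return A tibble with columns `i, j, betweenness` (`i < j`), one row per
#'   existing edge.
#' @export
edge_betweenness_map <- function(net, convention = "inverse") {
  el <- edge_lengths(net, convention)
  if (igraph::ecount(el$graph) == 0) {
    return(tibble::tibble(i = integer(), j = integer(),
                          betweenness = numeric()))
  }
  eb <- igraph::edge_betweenness(el$graph, weights = el$lengths,
                                 directed = FALSE)
  ends <- igraph::ends(el$graph, igraph::E(el$graph), names = FALSE)
  tibble::tibble(i = pmin(ends[, 1], ends[, 2]),
                 j = pmax(ends[, 1], ends[, 2]),
                 betweenness = eb) |>
    dplyr::arrange(.data$i, .data$j)
}

#' Tidy table of graph metrics for one network
#'
#' @param net A [weighted_network()].
#' @param metrics Character vector choosing among `density`, `total_strength`,
#'   `median_connectivity`, `global_efficiency`, `local_efficiency`,
#'   `characteristic_path_length`, `clustering_coefficient`.
#' @return A tibble with columns `metric`, `value`, `weight_kind`.
#' @export
network_metrics <- function(net,
                            metrics = c("density", "total_strength",
                                        "median_connectivity",
                                        "global_efficiency",
                                        "local_efficiency",
                                        "characteristic_path_length",
                                        "clustering_coefficient")) {
  fns <- list(
    density = network_density,
    total_strength = total_strength,
    median_connectivity = function(x) if (n_edges(x) > 0) median_connectivity(x) else NA_real_,
    global_efficiency = global_efficiency,
    local_efficiency = local_efficiency,
    characteristic_path_length = characteristic_path_length,
    clustering_coefficient = clustering_coefficient
  )
  metrics <- match.arg(metrics, names(fns), several.ok = TRUE)
  tibble::tibble(
    metric = metrics,
    value = vapply(metrics, function(m) fns[[m]](net), numeric(1)),
    weight_kind = net$weight_kind
  )
}
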