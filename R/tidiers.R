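# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a small-world result
#'
#' @param x A [small_world()] object.
#' @param ... Unused.
#' @return One-row tibble with `alpha`, `gamma`, `sigma`.
#' @export
tidy.small_world <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, gamma = x$gamma, sigma = x$sigma,
                 sigma_form = x$sigma_form)
}

#' @rdname tidy.small_world
#' @export
glance.small_world <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, sigma_form = x$sigma_form,
                 n_random = x$n_random, seed = x$seed)
}

#' Tidy a core/local partition
#'
#' @param x A [identify_core()] result.
#' @param ... Unused.
#' @return Tibble of edges with a `role` column (`"core"`/`"local"`).
#' @export
tidy.core_local_partition <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$core, role = "core"),
    dplyr::mutate(x$local, role = "local")
  )
}

#' @rdname tidy.core_local_partition
#' @export
glance.core_local_partition <- function(x, ...) {
  tibble::tibble(n_core = nrow(x$core), n_local = nrow(x$local),
                 core_betweenness_share = x$core_betweenness_share,
                 share = x$share, all_zero = x$all_zero)
}

#' Tidy a density sweep
#'
#' @param x A [density_sweep()] result.
#' @param ... Unused.
#' @return The per-density tibble; `glance()` returns the cost-integrated
#'   summary.
#' @export
tidy.neoconn_sweep <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.neoconn_sweep
#' @export
glance.neoconn_sweep <- function(x, ...) attr(x, "cost_integrated")

#' Tidy an edge-wise statistics table
#'
#' @param x An [edgewise_association()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-edge tibble; `glance()`: edge counts and the FDR
#'   level.
#' @export
tidy.edgewise_stats <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.edgewise_stats
#' @export
glance.edgewise_stats <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x), n_significant = sum(x$significant),
                 q = attr(x, "q"), n_scans = attr(x, "n_scans"))
}

#' Plot a density sweep
#'
#' Metric value against network density, one panel per metric, with the
#' cost-integrated mean as a dashed reference line.
#'
#' @param object A [density_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neoconn_sweep <- function(object, ...) {
  ci <- attr(object, "cost_integrated")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$density, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = ci,
                        ggplot2::aes(yintercept = .data$cost_integrated),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "network density (cost)", y = "metric value") +
    ggplot2::theme_minimal()
}

#' Plot edge-wise association results
#'
#' Correlation coefficient against `-log10(q)` for every grid edge,
#' significant edges highlighted.
#'
#' @param object An [edgewise_association()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edgewise_stats <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rho, y = -log10(pmax(.data$q_value, 1e-16)),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "partial Spearman rho", y = "-log10(q)",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot cohort raw density against age at scan
#'
#' Raw network density (after the streamline filter) of every scan against
#' post-menstrual age, the cohort-level summary the generator is calibrated
#' to.
#'
#' @param object A `neoconn_cohort` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neoconn_cohort <- function(object, ...) {
  dens <- vapply(object$connectome,
                 function(cn) network_density(build_network(cn, "BINARY")),
                 numeric(1))
  df <- tibble::tibble(pma_scan = object$pma_scan, density = dens)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pma_scan, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "PMA at scan (weeks)", y = "raw network density") +
    ggplot2::theme_minimal()
}
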