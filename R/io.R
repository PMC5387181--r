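# Readers and writers for cohort metadata and connectomes. Two documented CSV
# dialects: "long" (one edge table per scan: i, j, count, fa, ndi, odi) and
# "matrix" (four labelled square matrices per scan). Indices are 1-based with
# region labels in all files; edges are written with i < j.

# write a data frame with doubles in shortest-exact %.17g form so the long
# dialect round-trips bit-identically through strtod-based read.csv
write_exact_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a cohort to disk
#'
#' Writes `metadata.csv` (one row per scan) plus per-scan connectome files in
#' the chosen dialect under `dir/connectomes/`. The long dialect round-trips
#' bit-identically through [read_cohort()].
#'
#' @param cohort A `neoconn_cohort` tibble.
#' @param dir Output directory (created if needed).
#' @param dialect `"long"` (edge table) or `"matrix"` (four matrix CSVs).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = c("long", "matrix")) {
  dialect <- match.arg(dialect)
  cdir <- file.path(dir, "connectomes")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  meta <- dplyr::select(tibble::as_tibble(cohort), -"connectome")
  write_exact_csv(meta, file.path(dir, "metadata.csv"))
  for (k in seq_len(nrow(cohort))) {
    conn <- cohort$connectome[[k]]
    id <- cohort$scan_id[k]
    if (dialect == "long") {
      write_exact_csv(connectome_edges(conn),
                      file.path(cdir, paste0(id, "_edges.csv")))
    } else {
      for (nm in c("counts", "fa", "ndi", "odi")) {
        m <- conn[[nm]]
        dimnames(m) <- list(conn$node_labels, conn$node_labels)
        utils::write.csv(m, file.path(cdir, paste0(id, "_", nm, ".csv")))
      }
    }
  }
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Reads `metadata.csv` and the per-scan connectome files written by
#' [write_cohort()] (either dialect, auto-detected). All connectome invariants
#' are validated on load; asymmetries beyond 1e-9 and out-of-range
#' microstructure are errors identifying the offending edge.
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `neoconn_cohort` tibble.
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in ", dir, call. = FALSE)
  meta <- tibble::as_tibble(utils::read.csv(meta_path))
  meta$sex <- factor(meta$sex, levels = c("F", "M"))
  cdir <- file.path(dir, "connectomes")
  meta$connectome <- lapply(meta$scan_id, function(id) {
    long <- file.path(cdir, paste0(id, "_edges.csv"))
    if (file.exists(long)) {
      edges <- tibble::as_tibble(utils::read.csv(long))
      n <- max(edges$j)
      # region labels are positional; rebuild the full label set
      lab <- default_node_labels(n)
      lab[edges$i] <- edges$region_i
      lab[edges$j] <- edges$region_j
      connectome_from_edges(edges, n, lab)
    } else {
      mats <- lapply(c("counts", "fa", "ndi", "odi"), function(nm) {
        p <- file.path(cdir, paste0(id, "_", nm, ".csv"))
        if (!file.exists(p)) stop("missing connectome file ", p, call. = FALSE)
        as.matrix(utils::read.csv(p, row.names = 1, check.names = FALSE))
      })
      names(mats) <- c("counts", "fa", "ndi", "odi")
      check_symmetry(mats$counts, id)
      multiweight_connectome(mats$counts, mats$fa, mats$ndi, mats$odi,
                             node_labels = rownames(mats$counts))
    }
  })
  class(meta) <- c("neoconn_cohort", class(meta))
  meta
}

check_symmetry <- function(m, id, tol = 1e-9) {
  dlt <- abs(m - t(m))
  dlt[is.na(dlt)] <- 0
  if (any(dlt > tol)) {
    bad <- which(dlt > tol, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: matrix asymmetric at edge (%d,%d)", id,
                 min(bad), max(bad)), call. = FALSE)
  }
  invisible(m)
}

#' Write a weighted network
#'
#' `write_network_csv()` writes the labelled weight matrix;
#' `write_network_graphml()` writes GraphML with the weight as an edge
#' attribute and the weight kind as a graph attribute.
#'
#' @param net A [weighted_network()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(net, path) {
  m <- net$weights
  dimnames(m) <- list(net$node_labels, net$node_labels)
  utils::write.csv(m, path)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::V(g)$name <- net$node_labels
  g <- igraph::set_graph_attr(g, "weight_kind", net$weight_kind)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
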