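# Brute-force reference implementations, independent of the package internals
# (and of igraph): plain-R Floyd-Warshall distances, exhaustive geodesic
# enumeration for betweenness, and direct metric definitions. Used as oracles
# on small graphs.

mk_net <- function(w, kind = "FS") weighted_network(w, kind)

bf_lengths <- function(w, kind) {
  len <- matrix(Inf, nrow(w), ncol(w))
  if (kind == "BINARY") len[w > 0] <- 1 else len[w > 0] <- 1 / w[w > 0]
  diag(len) <- 0
  len
}

bf_distances <- function(w, kind = "FS") {
  d <- bf_lengths(w, kind)
  n <- nrow(w)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

bf_density <- function(w) {
  n <- nrow(w)
  sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}

bf_eglob <- function(w, kind = "FS") {
  n <- nrow(w)
  d <- bf_distances(w, kind)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

bf_lp <- function(w, kind = "FS") {
  d <- bf_distances(w, kind)
  off <- d[row(d) != col(d)]
  off <- off[is.finite(off)]
  if (length(off) == 0) return(NA_real_)
  mean(off)
}

bf_eloc <- function(w, kind = "FS") {
  n <- nrow(w)
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(w[v, ] > 0)
    if (length(nb) < 2) return(0)
    bf_eglob(w[nb, nb, drop = FALSE], kind)
  }, numeric(1))
  mean(vals)
}

bf_cp <- function(w, kind = "FS") {
  n <- nrow(w)
  wh <- if (kind == "BINARY") (w > 0) * 1 else (w / max(w))^(1 / 3)
  k <- rowSums(w > 0)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) s <- s + wh[i, j] * wh[i, h] * wh[j, h]
    }
    ci[i] <- s / (k[i] * (k[i] - 1))
  }
  mean(ci)
}

# all simple paths from a to b with their total lengths
bf_paths <- function(len, a, b) {
  n <- nrow(len)
  out <- list()
  walk <- function(path, total) {
    v <- path[length(path)]
    if (v == b) {
      out[[length(out) + 1]] <<- list(path = path, length = total)
      return()
    }
    for (u in seq_len(n)) {
      if (is.finite(len[v, u]) && u != v && !(u %in% path)) {
        walk(c(path, u), total + len[v, u])
      }
    }
  }
  walk(a, 0)
  out
}

# exhaustive edge betweenness: for every unordered node pair, enumerate all
# simple paths, keep the co-minimal ones (relative tolerance), and credit each
# edge fractionally
bf_edge_betweenness <- function(w, kind = "FS", tol = 1e-12) {
  n <- nrow(w)
  len <- bf_lengths(w, kind)
  diag(len) <- Inf
  eb <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    paths <- bf_paths(len, a, b)
    if (length(paths) == 0) next
    lens <- vapply(paths, function(p) p$length, numeric(1))
    mn <- min(lens)
    geo <- paths[lens <= mn * (1 + tol) + tol]
    for (p in geo) {
      pp <- p$path
      for (s in seq_len(length(pp) - 1)) {
        i <- min(pp[s], pp[s + 1]); j <- max(pp[s], pp[s + 1])
        eb[i, j] <- eb[i, j] + 1 / length(geo)
      }
    }
  }
  eb
}

# random connected-ish weighted graph on n nodes; continuous weights so
# geodesic ties have probability zero
random_graph <- function(n, p = 0.5, kind = "FS") {
  m <- n * (n - 1) / 2
  repeat {
    present <- stats::runif(m) < p
    if (any(present)) break
  }
  w_ut <- ifelse(present, stats::runif(m, 0.2, 1), 0)
  if (kind == "BINARY") w_ut <- (w_ut > 0) * 1
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- w_ut
  w + t(w)
}

# small connectome fixture built directly from matrices
toy_connectome <- function(counts, ndi = NULL) {
  n <- nrow(counts)
  fill <- function(base) {
    m <- matrix(NA_real_, n, n)
    m[counts > 0] <- base
    m
  }
  ndi <- if (is.null(ndi)) fill(0.5) else ndi
  multiweight_connectome(counts, fa = fill(0.3), ndi = ndi, odi = fill(0.4))
}

small_cohort <- function(n_subjects = 6, n_repeat = 1, nodes = 20, seed = 11) {
  simulate_cohort(cohort_config(n_subjects = n_subjects,
                                n_repeat_scans = n_repeat,
                                node_count = nodes, seed = seed))
}
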