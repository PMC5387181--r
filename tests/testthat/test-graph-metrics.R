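# Graph metrics: worked examples, conventions, and spot oracle agreement.
# The exhaustive 200-graph oracle sweep lives in the acceptance suite.

path3 <- function() {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  weighted_network(w, "BINARY")
}

test_that("density counts existing edges over possible edges", {
  expect_equal(n_possible_edges(91), 4095L)
  full <- weighted_network(1 - diag(91), "BINARY")
  expect_equal(network_density(full), 1)
  empty <- weighted_network(matrix(0, 5, 5), "BINARY")
  expect_equal(network_density(empty), 0)
  # a 505-edge network on 91 nodes
  w <- matrix(0, 91, 91)
  idx <- which(upper.tri(w))[1:505]
  w[idx] <- 1; w <- w + t(w)
  expect_equal(network_density(weighted_network(w, "BINARY")), 505 / 4095)
})

test_that("geodesics use inverse-weight lengths", {
  expect_equal(graph_distances(path3())[1, 3], 2)
  tri <- weighted_network(2 * (1 - diag(3)), "FS")
  d <- graph_distances(tri)
  expect_true(all(d[upper.tri(d)] == 0.5))
  # disconnected pairs are infinite
  w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 1
  expect_equal(graph_distances(weighted_network(w, "BINARY"))[1, 3], Inf)
  neg <- weighted_network(matrix(0, 3, 3), "FS")
  neg$weights[1, 2] <- neg$weights[2, 1] <- -1
  expect_error(graph_distances(neg), "negative")
})

test_that("global efficiency matches direct evaluation", {
  expect_equal(global_efficiency(path3()), 5 / 6)
  full <- weighted_network(1 - diag(6), "BINARY")
  expect_equal(global_efficiency(full), 1)
  expect_equal(global_efficiency(weighted_network(matrix(0, 4, 4), "BINARY")), 0)
})

test_that("local efficiency follows the neighbourhood-subgraph definition", {
  tri <- weighted_network(1 - diag(3), "BINARY")
  expect_equal(local_efficiency(tri), 1)
  expect_equal(local_efficiency(path3()), 0)
  expect_equal(local_efficiency(weighted_network(matrix(0, 4, 4), "BINARY")), 0)
})

test_that("path length and clustering use the documented conventions", {
  expect_equal(characteristic_path_length(path3()), 4 / 3)
  expect_equal(clustering_coefficient(path3()), 0)
  full <- weighted_network(1 - diag(5), "BINARY")
  expect_equal(characteristic_path_length(full), 1)
  expect_equal(clustering_coefficient(full), 1)
})

test_that("edge betweenness matches brute force on canonical graphs", {
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  eb <- edge_betweenness_map(weighted_network(star, "BINARY"))
  expect_equal(eb$betweenness, rep(3, 3))
  tri <- weighted_network(1 - diag(3), "BINARY")
  expect_equal(edge_betweenness_map(tri)$betweenness, rep(1, 3))
  two <- matrix(0, 2, 2); two[1, 2] <- two[2, 1] <- 0.4
  expect_equal(edge_betweenness_map(weighted_network(two, "FA"))$betweenness, 1)
})

test_that("metrics agree with brute-force references on random graphs", {
  withr::with_seed(404, {
    for (rep in 1:25) {
      n <- sample(4:7, 1)
      kind <- sample(c("FS", "BINARY"), 1)
      w <- random_graph(n, kind = kind)
      net <- mk_net(w, kind)
      expect_equal(network_density(net), bf_density(w), tolerance = 1e-9)
      expect_equal(global_efficiency(net), bf_eglob(w, kind), tolerance = 1e-9)
      expect_equal(local_efficiency(net), bf_eloc(w, kind), tolerance = 1e-9)
      expect_equal(characteristic_path_length(net), bf_lp(w, kind),
                   tolerance = 1e-9)
      expect_equal(clustering_coefficient(net), bf_cp(w, kind),
                   tolerance = 1e-9)
      eb <- edge_betweenness_map(net)
      ebm <- bf_edge_betweenness(w, kind)
      expect_equal(eb$betweenness, ebm[cbind(eb$i, eb$j)], tolerance = 1e-9)
    }
  })
})

test_that("weighted efficiency scales linearly with a global weight rescale", {
  withr::with_seed(7, w <- random_graph(6))
  e1 <- global_efficiency(mk_net(w))
  e3 <- global_efficiency(mk_net(3 * w))
  expect_equal(e3, 3 * e1, tolerance = 1e-12)
})

test_that("adding an edge never decreases binary global efficiency", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      w <- random_graph(6, p = 0.4, kind = "BINARY")
      absent <- which(upper.tri(w) & w == 0)
      if (length(absent) == 0) next
      e0 <- global_efficiency(mk_net(w, "BINARY"))
      w2 <- w
      pick <- sample(absent, 1)
      w2[pick] <- 1
      w2 <- pmax(w2, t(w2))
      expect_gte(global_efficiency(mk_net(w2, "BINARY")), e0 - 1e-12)
    }
  })
})

test_that("binary local efficiency lies in [0, 1]", {
  withr::with_seed(19, {
    for (rep in 1:10) {
      w <- random_graph(7, p = stats::runif(1, 0.2, 0.9), kind = "BINARY")
      el <- local_efficiency(mk_net(w, "BINARY"))
      expect_gte(el, 0); expect_lte(el, 1)
    }
  })
})
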