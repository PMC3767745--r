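path4 <- function() {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 3] <- w[3, 4] <- 1
  w + t(w)
}

star <- function(n) {
  w <- matrix(0, n, n)
  w[1, 2:n] <- 1
  w + t(w)
}

triangle <- function(wab = 1, wbc = 1, wac = 1) {
  w <- matrix(0, 3, 3)
  w[1, 2] <- wab; w[2, 3] <- wbc; w[1, 3] <- wac
  w + t(w)
}

test_that("degrees count nonzero neighbours", {
  full <- matrix(0.5, 18, 18); diag(full) <- 0
  expect_identical(unname(node_degrees(full)), rep(17, 18))
  expect_identical(unname(node_degrees(matrix(0, 4, 4))), rep(0, 4))
  expect_identical(unname(node_degrees(path4())), c(1, 2, 2, 1))
})

test_that("clustering follows the cube-root product form", {
  expect_identical(clustering_coefficient(triangle())$mean, 1)
  expect_identical(clustering_coefficient(star(6))$mean, 0)
  got <- clustering_coefficient(triangle(1, 1, 0.5))
  expect_equal(unname(got$by_node), rep(0.5^(1 / 3), 3), tolerance = 1e-12)
  ## max-normalized variant rescales by the largest weight
  half <- clustering_coefficient(triangle(0.5, 0.5, 0.25), normalize = "max")
  expect_equal(half$mean, 0.5^(1 / 3), tolerance = 1e-12)
  expect_error(clustering_coefficient(triangle(2, 1, 1)), "exceed 1")
})

test_that("shortest paths use inverse-weight lengths", {
  two <- matrix(c(0, .5, .5, 0), 2)
  expect_equal(shortest_path_lengths(two)[1, 2], 2)
  ## detour through the chain beats the weak direct edge
  w <- triangle(1, 1, 0.4)
  L <- shortest_path_lengths(w)
  expect_equal(L[1, 3], 2) # via node 2: 1 + 1 < 1 / 0.4
  disc <- matrix(0, 3, 3); disc[1, 2] <- disc[2, 1] <- 1
  expect_identical(shortest_path_lengths(disc)[1, 3], Inf)
  expect_identical(diag(shortest_path_lengths(disc)), rep(0, 3))
})

test_that("characteristic path length and efficiency are exact inverses", {
  full <- matrix(1, 5, 5); diag(full) <- 0
  expect_equal(characteristic_path_length(full), 1)
  expect_equal(global_efficiency(full), 1)
  two <- matrix(c(0, .5, .5, 0), 2)
  expect_equal(characteristic_path_length(two), 2)
  expect_identical(global_efficiency(matrix(0, 3, 3)), 0)
  expect_warning(L <- characteristic_path_length(matrix(0, 3, 3)),
                 "disconnected")
  expect_true(is.nan(L))
  expect_equal(global_efficiency(star(4)), 0.75) # 6 direct + 6 two-hop pairs
  set.seed(40)
  for (i in 1:50) {
    w <- rand_connected_graph(sample(4:8, 1))
    expect_equal(global_efficiency(w) * characteristic_path_length(w), 1,
                 tolerance = 1e-12)
  }
})

test_that("local efficiency is the neighbour-subgraph global efficiency", {
  full <- matrix(1, 5, 5); diag(full) <- 0
  expect_identical(local_efficiency(full)$mean, 1)
  expect_identical(local_efficiency(star(5))$mean, 0)
  tri_pendant <- matrix(0, 4, 4)
  tri_pendant[1, 2] <- tri_pendant[2, 3] <- tri_pendant[1, 3] <- 1
  tri_pendant[3, 4] <- 1
  tri_pendant <- tri_pendant + t(tri_pendant)
  el <- local_efficiency(tri_pendant)$by_node
  ## node 3's neighbour subgraph {1, 2, 4} has the single edge 1-2
  expect_equal(unname(el), c(1, 1, 1 / 3, 0))
})

test_that("all metrics agree with brute-force enumeration on small graphs", {
  set.seed(41)
  for (i in 1:60) {
    w <- rand_graph(sample(3:6, 1), p = runif(1, 0.3, 1))
    expect_equal(unname(shortest_path_lengths(w)), bf_shortest_paths(w),
                 tolerance = 1e-9)
    expect_equal(unname(clustering_coefficient(w)$by_node),
                 bf_clustering(w)$by_node, tolerance = 1e-9)
    expect_equal(global_efficiency(w), bf_global_eff(w), tolerance = 1e-9)
    expect_equal(unname(local_efficiency(w)$by_node),
                 bf_local_eff(w)$by_node, tolerance = 1e-9)
  }
})

test_that("shortest paths agree with an independent graph library", {
  set.seed(42)
  for (i in 1:15) {
    w <- rand_graph(8, 0.5)
    g <- igraph::graph_from_adjacency_matrix(ifelse(w > 0, 1 / w, 0),
                                             mode = "undirected",
                                             weighted = TRUE)
    expect_equal(unname(shortest_path_lengths(w)),
                 unname(igraph::distances(g)), tolerance = 1e-10)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(43)
  for (i in 1:30) {
    w <- rand_graph(6, 0.5)
    absent <- which(upper.tri(w) & w == 0)
    if (!length(absent)) next
    e <- sample(absent, 1)
    w2 <- w
    w2[e] <- 0.5
    w2 <- pmax(w2, t(w2))
    expect_gte(global_efficiency(w2), global_efficiency(w) - 1e-12)
  }
})

test_that("metrics remain finite on fragmented sub-networks", {
  w <- matrix(0, 6, 6)
  w[1, 2] <- w[2, 1] <- 0.8
  w[3, 4] <- w[4, 3] <- 0.3 # two components, two isolated nodes
  tm <- topology_metrics(w)
  expect_true(is.finite(tm$global_eff))
  expect_true(is.finite(tm$path_length))
  expect_identical(tm$clustering, 0)
  expect_equal(tm$mean_connectivity, 0.55)
  expect_identical(tm$n_edges, 2L)
})
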