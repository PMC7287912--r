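test_that("degree matches closed forms on canonical graphs", {
  expect_equal(unname(node_degree(complete_graph(4))), rep(3, 4))
  expect_equal(unname(node_degree(path_graph(3))), c(1, 2, 1))
  empty <- fc_graph(matrix(0L, 5, 5))
  expect_equal(unname(node_degree(empty)), rep(0, 5))
  set.seed(1)
  g <- random_graph(10, 0.4)
  expect_equal(sum(node_degree(g)), 2 * g$n_edges)
})

test_that("clustering coefficient counts neighbor-pair edges", {
  expect_equal(unname(node_clustering(complete_graph(4))), rep(1, 4))
  expect_equal(node_clustering(star_graph(5))[[1]], 0)
  # triangle 1-2-3 with pendant node 4 attached to vertex 1
  g <- graph_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3), c(1, 4)))
  expect_equal(unname(node_clustering(g)), c(1 / 3, 1, 1, 0))
})

test_that("shortest-path distances flag unreachable pairs", {
  d <- graph_distances(path_graph(3))
  expect_equal(d[1, 3], 2)
  two_edges <- graph_from_edges(4, list(c(1, 2), c(3, 4)))
  d2 <- graph_distances(two_edges)
  expect_true(is.infinite(d2[1, 3]))
  expect_equal(d2[1, 2], 1)
  d5 <- graph_distances(cycle_graph(5))
  expect_equal(max(d5), 2)
  expect_equal(d5, t(d5))
})

test_that("nodal average path length averages over reachable peers", {
  expect_equal(node_avg_path_length(path_graph(3))[[1]], 1.5)
  expect_equal(node_avg_path_length(star_graph(5))[[2]], 1.75) # a leaf
  expect_equal(unname(node_avg_path_length(complete_graph(6))), rep(1, 6))
  with_isolate <- graph_from_edges(3, list(c(1, 2)))
  expect_warning(apl <- node_avg_path_length(with_isolate), "Isolated")
  expect_true(is.na(apl[[3]]))
})

test_that("characteristic path length matches pair enumeration", {
  expect_equal(characteristic_path_length(path_graph(3)), 4 / 3)
  expect_equal(characteristic_path_length(cycle_graph(5)), 1.5)
  expect_equal(characteristic_path_length(complete_graph(7)), 1)
  expect_error(characteristic_path_length(fc_graph(matrix(0L, 3, 3))), "no edges")
})

test_that("global efficiency treats unreachable peers as zero contribution", {
  expect_equal(node_global_efficiency(path_graph(3))[[1]], 0.75)
  expect_equal(unname(node_global_efficiency(complete_graph(5))), rep(1, 5))
  with_isolate <- graph_from_edges(5, list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(node_global_efficiency(with_isolate)[[5]], 0)
})

test_that("local efficiency is the efficiency of the neighbor subgraph", {
  expect_equal(unname(node_local_efficiency(complete_graph(4))), rep(1, 4))
  expect_equal(node_local_efficiency(star_graph(5))[[1]], 0)
  expect_equal(node_local_efficiency(path_graph(3))[[2]], 0)
})

test_that("betweenness matches hand enumeration on canonical graphs", {
  expect_equal(unname(node_betweenness(path_graph(3))), c(0, 1, 0))
  expect_equal(node_betweenness(star_graph(5))[[1]], 6) # C(4,2) leaf pairs
  expect_equal(unname(node_betweenness(cycle_graph(5))), rep(1, 5))
  expect_equal(node_betweenness(star_graph(5), normalized = TRUE)[[1]], 1)
})

test_that("every metric matches the igraph oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (rep in 1:80) {
    g <- random_graph(sample(5:8, 1), stats::runif(1, 0.1, 0.95))
    expect_metrics_match(package_metric_vectors(g), igraph_metric_oracle(g))
  }
})

test_that("every metric matches brute-force path enumeration on small graphs", {
  set.seed(100)
  for (rep in 1:25) {
    g <- random_graph(sample(4:6, 1), stats::runif(1, 0.2, 0.95))
    expect_metrics_match(package_metric_vectors(g), bf_metric_oracle(g))
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(12)
  for (rep in 1:20) {
    g <- random_graph(7, 0.5)
    perm <- sample(7)
    gp <- fc_graph(g$adjacency[perm, perm])
    mine <- package_metric_vectors(g)
    permuted <- package_metric_vectors(gp)
    for (nm in names(mine)) {
      expect_equal(permuted[[nm]], mine[[nm]][perm], tolerance = 1e-12)
    }
  }
})

test_that("leaf nodes have zero betweenness and metrics stay in bounds", {
  set.seed(13)
  for (rep in 1:20) {
    g <- random_graph(8, stats::runif(1, 0.2, 0.8))
    mv <- package_metric_vectors(g)
    leaves <- which(mv$degree == 1)
    expect_true(all(mv$betweenness[leaves] == 0))
    expect_true(all(mv$clustering >= 0 & mv$clustering <= 1))
    expect_true(all(mv$local_efficiency >= 0 & mv$local_efficiency <= 1))
    expect_true(all(mv$global_efficiency >= 0 & mv$global_efficiency <= 1))
    expect_true(all(mv$betweenness >= 0))
    expect_true(all(mv$average_path_length >= 1, na.rm = TRUE))
  }
})

test_that("characteristic path length is the reachable-pair-weighted nodal mean", {
  set.seed(14)
  for (rep in 1:20) {
    g <- random_graph(8, stats::runif(1, 0.3, 0.9))
    if (g$n_edges == 0) next
    d <- graph_distances(g)
    diag(d) <- NA
    reach <- apply(d, 1, function(r) sum(is.finite(r), na.rm = TRUE))
    apl <- suppressWarnings(node_avg_path_length(g))
    keep <- reach > 0
    expect_equal(
      characteristic_path_length(g),
      sum(apl[keep] * reach[keep]) / sum(reach[keep])
    )
  }
})

test_that("graph_metrics assembles all indexes into a tidy table", {
  g <- complete_graph(4)
  tab <- graph_metrics(g)
  expect_equal(names(tab),
               c("roi", "degree", "clustering_coefficient", "average_path_length",
                 "local_efficiency", "global_efficiency", "betweenness_centrality"))
  expect_equal(tab$degree, rep(3, 4))
  expect_equal(tab$average_path_length, rep(1, 4))
})
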