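test_that("density follows 2E / n(n-1)", {
  expect_equal(network_density(make_net(two_cliques(3, 1)[1:3, 1:3])), 1)
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 0.4
  w[3, 4] <- w[4, 3] <- 0.1
  expect_equal(network_density(make_net(w)), 0.2)
  expect_equal(network_density(make_net(matrix(0, 4, 4))), 0)
  expect_error(network_density(make_net(matrix(0, 1, 1))), "at least 2")
})

test_that("density and CV are invariant to weight rescaling", {
  set.seed(3)
  occ <- random_occurrence(20, 8)
  net <- assoc_network(occ)
  scaled <- net
  scaled$weights <- net$weights * 7.3
  expect_equal(network_density(scaled), network_density(net))
  expect_equal(cv_edge_weights(scaled), cv_edge_weights(net))
})

test_that("CV of edge weights matches direct recomputation", {
  w <- matrix(0.3, 4, 4)
  diag(w) <- 0
  expect_equal(cv_edge_weights(make_net(w)), 0)

  # dyad values {2, 4} once the zero pair is excluded
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 2
  w2[1, 3] <- w2[3, 1] <- 4
  expect_equal(cv_edge_weights(make_net(w2), include_zeros = FALSE),
               sd(c(2, 4)) / 3, tolerance = 1e-12)
  expect_equal(round(cv_edge_weights(make_net(w2), include_zeros = FALSE), 4),
               0.4714)

  set.seed(8)
  net <- assoc_network(random_occurrence(25, 9))
  v <- net$weights[upper.tri(net$weights)]
  expect_equal(cv_edge_weights(net), sd(v) / mean(v))
  expect_error(cv_edge_weights(make_net(matrix(0, 3, 3))), "undefined")
})

test_that("betweenness matches hand-computed small graphs", {
  # path a - b - c
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- w[2, 3] <- w[3, 2] <- 0.5
  b <- node_betweenness(make_net(w))
  expect_equal(unname(b), c(0, 1, 0))

  # star: centre bridges all 6 leaf pairs
  w <- matrix(0, 5, 5)
  w[1, 2:5] <- w[2:5, 1] <- 0.25
  b <- node_betweenness(make_net(w))
  expect_equal(unname(b), c(6, 0, 0, 0, 0))

  # 4-cycle: two equally short paths between opposite corners split credit
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- w[2, 3] <- w[3, 2] <- 0.5
  w[3, 4] <- w[4, 3] <- w[4, 1] <- w[1, 4] <- 0.5
  b <- node_betweenness(make_net(w))
  expect_equal(unname(b), rep(0.5, 4))
})

test_that("betweenness agrees with exhaustive path enumeration", {
  set.seed(11)
  for (mode in c("cost", "similarity_reciprocal")) {
    for (n in 3:7) {
      net <- random_connected_net(n, mode)
      expect_equal(node_betweenness(net, mode),
                   oracle_betweenness(net$weights, mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("modularity follows the weighted Newman formula", {
  net <- make_net(two_cliques(3, 1))
  split_part <- rep(1:2, each = 3)
  expect_equal(newman_modularity(net, split_part), 0.5)
  expect_equal(newman_modularity(net, rep(1, 6)), 0)
  # named assignment in arbitrary order
  named <- setNames(split_part, net$nodes)[sample(6)]
  expect_equal(newman_modularity(net, named), 0.5)
  # bound holds for arbitrary partitions of random networks
  set.seed(21)
  for (r in 1:20) {
    rnet <- assoc_network(random_occurrence(15, 7))
    a <- sample(1:3, 7, replace = TRUE)
    q <- newman_modularity(rnet, a)
    expect_true(q >= -0.5 && q <= 1)
    # cross-check against the reference implementation
    g <- as_igraph(rnet)
    q_ref <- igraph::modularity(g, a[match(igraph::V(g)$name, rnet$nodes)],
                                weights = igraph::E(g)$weight)
    expect_equal(q, q_ref, tolerance = 1e-12)
  }
})

test_that("walktrap recovers obvious block structure", {
  net <- make_net(two_cliques(3, 0.8))
  part <- walktrap_communities(net)
  expect_equal(part$n_modules, 2L)
  expect_equal(part$modularity, 0.5)
  expect_equal(length(unique(part$assignment[1:3])), 1L)
  expect_equal(length(unique(part$assignment[4:6])), 1L)

  # single clique: no substructure
  part1 <- walktrap_communities(make_net(two_cliques(3, 1)[1:3, 1:3]))
  expect_equal(part1$n_modules, 1L)
  expect_equal(part1$modularity, 0)
})

test_that("walktrap partition is never worse than no partition", {
  set.seed(33)
  for (r in 1:10) {
    net <- assoc_network(random_occurrence(25, 10))
    part <- walktrap_communities(net)
    expect_gte(part$modularity, 0)
    expect_setequal(names(part$assignment), net$nodes)
  }
})

test_that("metrics report bundles the individual statistics", {
  set.seed(5)
  net <- assoc_network(random_occurrence(30, 8))
  m <- network_metrics(net)
  expect_equal(m$density, network_density(net))
  expect_equal(m$cv_edge_weights, cv_edge_weights(net))
  expect_equal(m$betweenness, node_betweenness(net))
  expect_equal(m$partition$modularity,
               newman_modularity(net, m$partition$assignment))
  tab <- betweenness_table(net)
  expect_true(all(diff(tab$betweenness) <= 0))
})
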