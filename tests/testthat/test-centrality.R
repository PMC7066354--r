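chain_net <- function(w1 = 0.5, w2 = 0.5) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- w1
  W[2, 3] <- W[3, 2] <- w2
  weighted_network(W, c("A", "B", "C"))
}

test_that("edge lengths are reciprocal absolute weights", {
  net <- chain_net(0.5, -0.2)
  L <- edge_lengths(net)
  expect_equal(L["A", "B"], 2)
  expect_equal(L["B", "C"], 5)   # negative weight: absolute-value convention
  expect_equal(L["A", "C"], Inf)
  expect_equal(unname(diag(L)), rep(0, 3))
})

test_that("shortest paths count tied geodesics and flag unreachable pairs", {
  sp <- shortest_paths(edge_lengths(chain_net()))
  expect_equal(sp$D["A", "C"], 4)
  expect_equal(sp$sigma["A", "C"], 1)
  expect_equal(sp$through["B", "A", "C"], 1)

  # square with equal weights: two geodesics between opposite corners
  W <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    W[e[1], e[2]] <- W[e[2], e[1]] <- 0.5
  }
  sq <- shortest_paths(edge_lengths(weighted_network(W, LETTERS[1:4])))
  expect_equal(sq$D["A", "C"], 4)
  expect_equal(sq$sigma["A", "C"], 2)
  expect_equal(sq$through["B", "A", "C"], 1)
  expect_equal(sq$through["D", "A", "C"], 1)

  # disconnected pair
  W2 <- matrix(0, 3, 3); W2[1, 2] <- W2[2, 1] <- 0.4
  dp <- shortest_paths(edge_lengths(weighted_network(W2)))
  expect_equal(dp$D[1, 3], Inf)
  expect_equal(dp$sigma[1, 3], 0)
})

test_that("strength sums absolute weights by default", {
  net <- chain_net(0.5, -0.2)
  expect_equal(node_strength(net), c(A = 0.5, B = 0.7, C = 0.2))
  expect_equal(node_strength(net, absolute = FALSE)[["B"]], 0.3)
  # star centre with 6 edges of 0.3
  W <- matrix(0, 7, 7); W[1, 2:7] <- W[2:7, 1] <- 0.3
  expect_equal(unname(node_strength(weighted_network(W))[1]), 1.8)
  # isolated node
  expect_equal(unname(node_strength(weighted_network(matrix(0, 3, 3)))), rep(0, 3))
})

test_that("betweenness counts geodesic fractions through a node", {
  expect_equal(node_betweenness(chain_net(0.3, 0.8)),
               c(A = 0, B = 1, C = 0))
  # complete graph, equal weights: the direct edge always wins
  W <- matrix(0.4, 5, 5); diag(W) <- 0
  expect_equal(unname(node_betweenness(weighted_network(W))), rep(0, 5))
  # empty network
  expect_equal(unname(node_betweenness(weighted_network(matrix(0, 4, 4)))),
               rep(0, 4))
  # star centre attains the (p-1)(p-2)/2 upper bound
  Ws <- matrix(0, 7, 7); Ws[1, 2:7] <- Ws[2:7, 1] <- 0.3
  b <- node_betweenness(weighted_network(Ws))
  expect_equal(unname(b[1]), 15)
  expect_true(all(b <= 15))
})

test_that("closeness is inverse mean distance, zero when any peer is unreachable", {
  cl <- node_closeness(chain_net(0.5, 0.5))
  expect_equal(cl, c(A = 1/3, B = 0.5, C = 1/3))
  # complete graph, all weights 1 is excluded (|w| < 1); use lengths directly
  W <- matrix(0.5, 4, 4); diag(W) <- 0
  expect_equal(unname(node_closeness(weighted_network(W))), rep(0.5, 4))
  # any unreachable node zeroes strict closeness; component variant does not
  W2 <- matrix(0, 4, 4); W2[1, 2] <- W2[2, 1] <- 0.5
  net2 <- weighted_network(W2)
  expect_equal(unname(node_closeness(net2)), rep(0, 4))
  expect_equal(unname(node_closeness(net2, disconnected = "component")),
               c(0.5, 0.5, 0, 0))
})

test_that("profiles bundle the indices and are equivariant to relabelling", {
  net <- chain_net()
  pr <- centrality_profile(net)
  expect_equal(pr$strength, c(0.5, 1.0, 0.5))
  expect_equal(pr$betweenness, c(0, 1, 0))
  expect_equal(pr$closeness, c(1/3, 0.5, 1/3))
  expect_equal(nrow(centrality_long(pr)), 9)

  # permuting node labels permutes the profile identically
  set.seed(14)
  net6 <- random_network(6, seed = 14)
  perm <- c(3, 1, 6, 4, 2, 5)
  net_p <- weighted_network(net6$W[perm, perm], net6$nodes[perm])
  pr1 <- centrality_profile(net6)
  pr2 <- centrality_profile(net_p)
  expect_equal(pr2[match(pr1$node, pr2$node), -1], pr1[, -1],
               ignore_attr = TRUE, tolerance = 1e-12)

  # empty 7-node network: all zeros
  empty <- centrality_profile(weighted_network(matrix(0, 7, 7)))
  expect_true(all(empty[, -1] == 0))
})

test_that("scale covariance: weights times c scale strength/closeness, not betweenness", {
  net <- random_network(6, seed = 77, density = 0.7)
  pr <- centrality_profile(net)
  c_ <- 0.5
  pr2 <- centrality_profile(weighted_network(net$W * c_, net$nodes))
  expect_equal(pr2$strength, pr$strength * c_, tolerance = 1e-12)
  expect_equal(pr2$closeness, pr$closeness * c_, tolerance = 1e-12)
  expect_equal(pr2$betweenness, pr$betweenness, tolerance = 1e-12)
})

test_that("adding an edge never decreases strength or closeness", {
  for (s in 1:5) {
    net <- random_network(6, seed = 100 + s, density = 0.4)
    W2 <- net$W
    free <- which(upper.tri(W2) & W2 == 0)
    if (!length(free)) next
    idx <- free[1]
    W2[idx] <- 0.6
    W2[lower.tri(W2)] <- t(W2)[lower.tri(W2)]
    net2 <- weighted_network(W2, net$nodes)
    expect_true(all(node_strength(net2) >= node_strength(net) - 1e-12))
    expect_true(all(node_closeness(net2) >= node_closeness(net) - 1e-12))
  }
})

test_that("centralities agree with brute-force path enumeration on random graphs", {
  for (s in 1:40) {
    p <- 3 + (s %% 4)
    net <- random_network(p, seed = 2000 + s)
    pr <- centrality_profile(net)
    orc <- oracle_centrality(net$W)
    expect_equal(pr$strength, unname(orc$strength), tolerance = 1e-9)
    expect_equal(pr$betweenness, orc$betweenness, tolerance = 1e-9)
    expect_equal(pr$closeness, orc$closeness, tolerance = 1e-9)
    # igraph distances as an extra cross-check on the metric
    g <- igraph::graph_from_adjacency_matrix(abs(net$W), mode = "undirected",
                                             weighted = TRUE)
    igd <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    sp <- shortest_paths(edge_lengths(net))
    expect_equal(unname(sp$D), unname(igd), tolerance = 1e-9)
  }
})
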