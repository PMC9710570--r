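# Expression-biased random walk with restart: stationary distribution,
# directed edge fluxes and per-age snapshots.

lineGraph <- function(nodes) {
  igraph::graph_from_data_frame(
    data.frame(a = nodes[-length(nodes)], b = nodes[-1]),
    directed = FALSE, vertices = nodes)
}

test_that("two equal-score nodes share the stationary mass and flux", {
  net <- lineGraph(c("a", "b"))
  for (r in c(0.1, 0.5, 0.9)) {
    res <- netwalkEdgeFlux(net, c(a = 1, b = 1), propagationConfig(restart = r))
    expect_equal(unname(res$pi), c(0.5, 0.5), tolerance = 1e-9)
    expect_equal(res$flux["a", "b"], 0.5, tolerance = 1e-9)
    expect_equal(res$flux["b", "a"], 0.5, tolerance = 1e-9)
  }
})

test_that("power iteration matches the dense linear solve", {
  net <- lineGraph(c("a", "b", "c"))
  scores <- c(a = 1, b = 1, c = 1)
  res <- netwalkEdgeFlux(net, scores, propagationConfig(restart = 0.5))
  expect_equal(res$pi, rwrDenseOracle(net, scores, 0.5), tolerance = 1e-8)

  withSeed(101, {
    for (s in 1:20) {
      net <- randomConnectedGraph(sample(10:30, 1))
      scores <- setNames(runif(igraph::vcount(net)), igraph::V(net)$name)
      scores[sample(length(scores), 2)] <- 0
      res <- netwalkEdgeFlux(net, scores)
      oracle <- rwrDenseOracle(net, scores, 0.5)
      expect_lt(max(abs(res$pi - oracle[names(res$pi)])), 1e-8)
    }
  })
})

test_that("stationary mass, transitions and fluxes are conserved", {
  withSeed(77, {
    net <- randomConnectedGraph(40)
    scores <- setNames(rexp(40), igraph::V(net)$name)
  })
  res <- netwalkEdgeFlux(net, scores)
  expect_equal(sum(res$pi), 1, tolerance = 1e-8)
  expect_equal(max(abs(Matrix::rowSums(res$P) - 1)), 0, tolerance = 1e-12)
  expect_equal(sum(res$flux), 1, tolerance = 1e-8)
})

test_that("propagation is exactly invariant to score rescaling", {
  withSeed(13, {
    net <- randomConnectedGraph(25)
    scores <- setNames(runif(25), igraph::V(net)$name)
  })
  a <- netwalkEdgeFlux(net, scores)
  b <- netwalkEdgeFlux(net, scores * 1e4)
  # ratio-defined quantities: invariant up to IEEE rounding of the inputs
  expect_equal(a$pi, b$pi, tolerance = 1e-13)
  expect_equal(as.matrix(a$flux), as.matrix(b$flux), tolerance = 1e-13)
})

test_that("a high-score star leaf draws strictly more flux", {
  for (nLeaves in c(4, 8)) {
    leaves <- sprintf("l%d", seq_len(nLeaves))
    net <- igraph::graph_from_data_frame(
      data.frame(a = "hub", b = leaves), directed = FALSE)
    scores <- setNames(rep(1, nLeaves + 1), c("hub", leaves))
    scores["l1"] <- 5
    res <- netwalkEdgeFlux(net, scores)
    w1 <- min(res$flux["hub", "l1"], res$flux["l1", "hub"])
    w2 <- min(res$flux["hub", "l2"], res$flux["l2", "hub"])
    expect_gt(w1, w2)
  }
})

test_that("propagation rejects bad inputs and reports non-convergence", {
  net <- lineGraph(c("a", "b", "c"))
  expect_error(netwalkEdgeFlux(net, c(a = 0, b = 0, c = 0)), "positive")
  expect_error(netwalkEdgeFlux(net, c(a = 1, b = 1)), "cover")
  disc <- igraph::graph_from_data_frame(
    data.frame(a = c("a", "c"), b = c("b", "d")), directed = FALSE)
  expect_error(netwalkEdgeFlux(disc, c(a = 1, b = 1, c = 1, d = 1)),
               "connected")
  expect_error(
    netwalkEdgeFlux(net, c(a = 1, b = 2, c = 3),
                    propagationConfig(maxIterations = 2)),
    "did not converge")
})

test_that("snapshots take the minimum directed flux per interaction", {
  net <- lineGraph(c("a", "b", "c"))
  scores <- c(a = 3, b = 1, c = 0.2)
  res <- netwalkEdgeFlux(net, scores)
  snap <- snapshotFromFlux(res, net, "25")
  e <- snapshotEdges(snap)
  w <- snapshotWeights(snap)[, 1]
  for (i in seq_len(nrow(e))) {
    expect_equal(w[i], min(res$flux[e[i, 1], e[i, 2]],
                           res$flux[e[i, 2], e[i, 1]]))
  }
  expect_equal(nrow(e), igraph::ecount(net))   # all base edges present
})

test_that("one snapshot per age in order, identical columns alike", {
  withSeed(5, net <- randomConnectedGraph(15))
  nodes <- sort(igraph::V(net)$name)
  scores <- matrix(runif(15 * 3) + 0.1, 15, 3,
                   dimnames = list(nodes, c("25", "35", "45")))
  scores[, 3] <- scores[, 1]
  prof <- AgeProfiles(scores)
  snaps <- inferSnapshots(net, prof)
  expect_equal(nSnapshots(snaps), 3)
  expect_equal(snapshotAges(snaps), c("25", "35", "45"))
  w <- snapshotWeights(snaps)
  expect_equal(w[, 1], w[, 3])
  expect_false(isTRUE(all.equal(w[, 1], w[, 2])))

  badProf <- AgeProfiles(scores[-1, , drop = FALSE])
  expect_error(inferSnapshots(net, badProf), "node set")
})
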