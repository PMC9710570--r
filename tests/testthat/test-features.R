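# Dynamic network features: signed splitting, sparsification, graphlet
# orbit counts and the nine-definition registry.

test_that("signed splitting partitions edges by weight sign", {
  dyn <- makeDyn(cbind(c("a", "b", "c"), c("b", "c", "d")),
                 matrix(c(50, -20, 0), 3, 1))
  parts <- splitSigned(dyn)
  expect_equal(igraph::ecount(parts$positive), 1)
  expect_equal(igraph::E(parts$positive)$weight, 50)
  expect_equal(igraph::ecount(parts$negative), 1)
  expect_equal(igraph::E(parts$negative)$weight, 20)
  # conservation: positive + negative + zero edges = base edges
  expect_equal(igraph::ecount(parts$positive) +
                 igraph::ecount(parts$negative) + 1, 3)

  zero <- makeDyn(cbind("a", "b"), matrix(0, 1, 1))
  partsZero <- splitSigned(zero)
  expect_equal(igraph::ecount(partsZero$positive), 0)
  expect_equal(igraph::ecount(partsZero$negative), 0)
})

test_that("edge thresholding keeps the top absolute weights", {
  dyn <- makeDyn(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "e")),
                 matrix(c(10, -20, 30, 40), 4, 1))
  top <- thresholdEdges(dyn, 1, theta = 25)
  expect_equal(igraph::ecount(top), 1)
  expect_equal(igraph::E(top)$weight, 40)

  all <- thresholdEdges(dyn, 1, theta = 100)
  expect_equal(igraph::ecount(all), 4)

  sparse <- makeDyn(cbind(c("a", "b"), c("b", "c")), matrix(c(0, 5), 2, 1))
  expect_equal(igraph::ecount(thresholdEdges(sparse, 1, theta = 100)), 1)

  empty <- makeDyn(cbind("a", "b"), matrix(0, 1, 1))
  expect_equal(igraph::ecount(thresholdEdges(empty, 1)), 0)
  expect_error(thresholdEdges(dyn, 1, theta = 0), "theta")
})

test_that("graphlet orbits match hand enumeration on canonical graphs", {
  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  o <- graphletOrbitCounts(tri)
  expect_equal(unname(o[, "orbit0"]), rep(2, 3))
  expect_equal(unname(o[, "orbit3"]), rep(1, 3))
  expect_equal(sum(o[, -c(1, 4)]), 0)

  path <- igraph::make_graph(~ a - b, b - c)
  o <- graphletOrbitCounts(path)
  expect_equal(o["a", "orbit1"], 1)
  expect_equal(o["c", "orbit1"], 1)
  expect_equal(o["b", "orbit2"], 1)
})

test_that("graphlet orbits equal brute-force subset enumeration", {
  withSeed(55, {
    for (rep in 1:5) {
      g <- igraph::sample_gnp(12, 0.3)
      igraph::V(g)$name <- sprintf("v%02d", 1:12)
      expect_equal(graphletOrbitCounts(g), orbitBruteForce(g))
    }
  })
})

test_that("the registry computes the documented nine definitions", {
  edges <- cbind(c("a", "a", "b", "c"), c("b", "c", "c", "d"))
  w <- matrix(c(50, -20, 10, 0,
                25, 25, -30, 5), 4, 2)
  dyn <- makeDyn(edges, w)

  wd <- featureValues(computeFeatureMatrix(dyn, "wdeg_signed"))
  expect_equal(unname(wd["a", ]), c(30, 50))      # 50 - 20 ; 25 + 25
  expect_equal(dim(wd), c(4, 2))                  # x - 1 = 2 coordinates

  wp <- featureValues(computeFeatureMatrix(dyn, "wdeg_pos"))
  wn <- featureValues(computeFeatureMatrix(dyn, "wdeg_neg"))
  expect_equal(unname(wp["a", 1]), 50)
  expect_equal(unname(wn["a", 1]), 20)

  orb <- computeFeatureMatrix(dyn, "orbits")
  expect_equal(ncol(featureValues(orb)), 15)
  expect_equal(featureValues(orb),
               graphletOrbitCounts(DynAgeNet:::.thresholdUnionGraph(dyn, 25)))

  tr <- featureValues(computeFeatureMatrix(dyn, "trend"))
  expect_equal(colnames(tr), c("slope", "mean", "variance"))
  expect_equal(unname(tr["a", "slope"]), 20)      # 30 -> 50 across 2 points
  expect_equal(unname(tr["a", "mean"]), 40)

  for (fid in c("clustering", "closeness", "eigenvector", "kcore")) {
    fv <- featureValues(computeFeatureMatrix(dyn, fid))
    expect_equal(dim(fv), c(4, 2))
    expect_true(all(is.finite(fv)))
  }

  expect_error(computeFeatureMatrix(dyn, "nope"), "registry")
})

test_that("all-zero subnetworks give zero weighted-degree features", {
  dyn <- makeDyn(cbind(c("a", "b"), c("b", "c")), matrix(0, 2, 3))
  for (fid in c("wdeg_signed", "wdeg_pos", "wdeg_neg")) {
    expect_true(all(featureValues(computeFeatureMatrix(dyn, fid)) == 0))
  }
  tr <- featureValues(computeFeatureMatrix(dyn, "trend"))
  expect_true(all(tr == 0))
})

test_that("features are equivariant under gene relabeling and deterministic", {
  withSeed(91, {
    g <- randomConnectedGraph(12)
    ends <- igraph::as_edgelist(g)
    w <- matrix(rnorm(nrow(ends) * 3, sd = 30), nrow(ends), 3)
  })
  w <- pmax(pmin(w, 100), -100)
  dyn <- makeDyn(ends, w)
  relabel <- setNames(sprintf("z%02d", rev(seq_along(sort(unique(c(ends)))))),
                      sort(unique(c(ends))))   # order-reversing relabeling
  dynR <- makeDyn(cbind(relabel[ends[, 1]], relabel[ends[, 2]]), w)
  for (fid in featureRegistry()) {
    a <- featureValues(computeFeatureMatrix(dyn, fid))
    b <- featureValues(computeFeatureMatrix(dynR, fid))
    expect_equal(unname(b[relabel[rownames(a)], ]), unname(a),
                 tolerance = 1e-10, label = fid)
    # determinism
    expect_identical(a, featureValues(computeFeatureMatrix(dyn, fid)))
  }
})
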