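# Prediction-set comparison and gene-group enrichment.

test_that("the common universe is the node-set intersection", {
  g1 <- igraph::make_graph(~ a - b, b - c)
  g2 <- igraph::make_graph(~ b - c, c - d)
  expect_equal(commonUniverse(list(g1, g2)), c("b", "c"))
  expect_equal(commonUniverse(list(g1)), c("a", "b", "c"))
  expect_equal(commonUniverse(list(g1, g1)), c("a", "b", "c"))
  g3 <- igraph::make_graph(~ x - y)
  expect_error(commonUniverse(list(g1, g3)), "no genes")
})

test_that("predictions split into true positives and novel predictions", {
  truth <- GroundTruth(c("a", "b"), c("c", "d"))
  sp <- splitTpNovel(c("a", "c"), truth)
  expect_equal(sp$truePositives, "a")
  expect_equal(sp$novel, "c")
  expect_length(splitTpNovel(c("a", "b"), truth)$novel, 0)
  expect_equal(length(sp$truePositives) + length(sp$novel), 2)
  expect_error(splitTpNovel(c("a", "z"), truth), "outside")
})

test_that("Jaccard index follows the set-overlap definition", {
  expect_equal(jaccardIndex(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccardIndex(c("a", "b"), c("b", "a")), 1)
  expect_equal(jaccardIndex(c("a"), c("b")), 0)
  expect_error(jaccardIndex(character(0), character(0)), "empty")
})

test_that("hypergeometric tail equals exhaustive enumeration", {
  # universe 6, both sets of size 3, full overlap: 1 of the C(6,3) = 20
  # equally likely draws
  expect_equal(hypergeomOverlapP(3, 3, 3, 6), 1 / 20)
  expect_equal(hypergeomOverlapP(3, 3, 0, 6), 1)
  expect_equal(hypergeomOverlapP(4, 2, 1, 8), hypergeomOverlapP(2, 4, 1, 8))
  for (U in c(5, 8)) {
    for (A in 1:U) {
      for (B in 1:U) {
        for (ov in max(0, A + B - U):min(A, B)) {
          expect_equal(hypergeomOverlapP(A, B, ov, U),
                       hypergeomEnumOracle(A, B, ov, U),
                       tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeomOverlapP(3, 3, 4, 6), "inconsistent")
})

test_that("pairwise overlaps report Jaccard, counts and unique predictions", {
  truth <- GroundTruth(c("a", "b", "c", "d"), c("w", "x", "y", "z"))
  preds <- list(s1 = c("a", "b", "w"), s2 = c("b", "c", "w"),
                s3 = c("c", "d", "x"))
  res <- pairwiseOverlaps(preds, truth)
  tp <- res$overlaps[res$overlaps$type == "true_positive", ]
  expect_equal(nrow(tp), 3)
  r12 <- tp[tp$idA == "s1" & tp$idB == "s2", ]
  expect_equal(r12$jaccard, 1 / 3)          # {a,b} vs {b,c}
  expect_equal(r12$overlap, 1)
  expect_true(all(res$overlaps$adjP >= res$overlaps$p - 1e-15))

  uq <- res$uniqueCounts
  expect_equal(uq$unique[uq$type == "true_positive"], c(1L, 0L, 1L))
  nov <- uq[uq$type == "novel", ]
  expect_equal(nov$unique[nov$id == "s3"], 1L)   # only s3 predicts x

  same <- pairwiseOverlaps(list(p = c("a", "w"), q = c("a", "w")), truth)
  expect_equal(same$overlaps$jaccard, c(1, 1))
  expect_true(all(same$uniqueCounts$unique == 0))
})

test_that("gene groups follow the predicted x label partition", {
  truth <- GroundTruth(c("a", "b"), c("c", "d"))
  groups <- assignGroups(list(n1 = c("a", "c"), n2 = character(0)), truth)
  g <- geneGroupList(groups)
  expect_equal(g$PredictedAging, "a")
  expect_equal(g$PredictedNonAging, "c")
  expect_equal(g$NotPredictedAging, "b")
  expect_equal(g$NotPredictedNonAging, "d")
  expect_setequal(unlist(g), labeledGenes(truth))

  none <- geneGroupList(assignGroups(list(n1 = character(0)), truth))
  expect_length(none$PredictedAging, 0)
  expect_length(none$PredictedNonAging, 0)
  expect_error(assignGroups(list(n1 = "zz"), truth), "outside")
})

test_that("enrichment tables flag significant overlaps consistently", {
  withSeed(41, {
    universe <- sprintf("u%03d", 1:60)
    truth <- GroundTruth(universe[1:10], universe[11:60])
    groups <- assignGroups(list(s = universe[c(1:6, 11:14)]), truth)
    sets <- GeneSetCollection(list(
      hit = universe[c(1:6, 11:14)],        # equals the predicted set
      miss = universe[41:50],
      outside = c("zzz", universe[30])))
  })
  tab <- enrichmentTable(groups, sets)
  hitRow <- tab[tab$set == "hit", ]
  predRows <- hitRow[hitRow$group %in% c("PredictedAging",
                                         "PredictedNonAging"), ]
  expect_true(all(predRows$p < 0.01))
  expect_equal(tab$significant, tab$adjP < 0.05)
  expect_true(all(tab$adjP >= tab$p - 1e-15))

  # disjoint group and set: overlap 0, p = 1
  missAging <- tab[tab$set == "miss" & tab$group == "PredictedAging", ]
  expect_equal(missAging$overlap, 0)
  expect_equal(missAging$p, 1)

  # sets are restricted to the universe before testing
  expect_equal(tab$setSize[tab$set == "outside"][1], 1)
})

test_that("enrichment p-values are calibrated under random groups", {
  withSeed(61, {
    universe <- sprintf("u%03d", 1:500)
    ps <- replicate(400, {
      grp <- sample(universe, 30)
      set <- sample(universe, 35)
      hypergeomOverlapP(30, 35, length(intersect(grp, set)), 500)
    })
  })
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.1)
})
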