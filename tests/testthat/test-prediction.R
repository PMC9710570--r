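# Stratified folds, cross-validated logistic regression, accuracy metrics,
# permutation significance and model selection.

sepFeatures <- function(truth, sd = 0.1, seedVal = 2) {
  genes <- labeledGenes(truth)
  withSeed(seedVal, {
    x <- rnorm(length(genes), sd = sd) +
      ifelse(genes %in% positives(truth), 5, -5)
  })
  FeatureMatrix(matrix(x, ncol = 1, dimnames = list(genes, "f1")), "sep")
}

test_that("folds are stratified, deterministic partitions", {
  truth <- GroundTruth(paste0("p", 1:2), paste0("n", 1:8))
  folds <- makeFolds(truth, k = 5, seed = 3)
  f <- foldIds(folds)
  expect_setequal(names(f), labeledGenes(truth))
  expect_true(all(table(f) == 2))
  expect_false(f["p1"] == f["p2"])          # positives in distinct folds
  expect_identical(foldIds(makeFolds(truth, k = 5, seed = 3)), f)
  expect_false(identical(foldIds(makeFolds(truth, k = 5, seed = 4)), f))

  big <- GroundTruth(paste0("p", 1:23), paste0("n", 1:101))
  fb <- foldIds(makeFolds(big, k = 5, seed = 1))
  posCounts <- table(fb[paste0("p", 1:23)])
  expect_lte(diff(range(posCounts)), 1)
  expect_lte(diff(range(table(fb))), 2)

  expect_error(makeFolds(GroundTruth("p1", paste0("n", 1:9)), k = 5),
               "too few labeled")
})

test_that("cross-validation scores every gene once and separates signal", {
  truth <- GroundTruth(paste0("p", 1:10), paste0("n", 1:60))
  folds <- makeFolds(truth, k = 5, seed = 7)
  out <- trainPredictCv(sepFeatures(truth), truth, folds)
  expect_setequal(names(predictionScores(out)), labeledGenes(truth))
  expect_false(anyNA(predictionScores(out)))
  expect_gte(cvMetrics(out)["aupr"], 0.99)
  expect_setequal(predictedGenes(out), positives(truth))
  expect_equal(nrow(foldMetrics(out)), 5)

  # a fold whose training data is single-class is rejected
  f <- foldIds(folds)
  f[positives(truth)] <- 0L                 # all positives in fold 0
  badFolds <- new("FoldAssignment", folds = f, k = 5L, seed = 1L)
  expect_error(trainPredictCv(sepFeatures(truth), truth, badFolds),
               "single class")

  expect_error(
    trainPredictCv(FeatureMatrix(matrix(0, 2, 1,
                                        dimnames = list(c("p1", "n1"),
                                                        "f1")),
                                 "tiny"),
                   truth, folds),
    "cover")
})

test_that("AUPR handles perfect, tied and degenerate rankings", {
  expect_equal(aucPR(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(aucPR(c(5, 1, 2, 3), c(TRUE, FALSE, FALSE, FALSE)), 1)
  expect_equal(aucPR(rep(0.4, 10), rep(c(TRUE, FALSE), c(3, 7))), 0.3)
  expect_error(aucPR(1:3, c(TRUE, TRUE, TRUE)), "positive and")

  # invariant under strictly monotone transforms of the scores
  withSeed(11, {
    s <- rnorm(50)
    y <- runif(50) < 0.3
  })
  y[1:2] <- c(TRUE, FALSE)
  expect_equal(aucPR(s, y), aucPR(exp(2 * s), y))
  expect_equal(aucPR(s, y), aucPR(rank(s), y))
})

test_that("precision/recall/F follow the confusion-matrix arithmetic", {
  truth <- GroundTruth(c("a", "b", "c", "d"), c("e", "f", "g"))
  # predicted {a, b, e}: TP 2, FP 1, FN 2
  m <- precisionRecallFscore(c("a", "b", "e"), truth)
  expect_equal(unname(m), c(2 / 3, 1 / 2, 4 / 7), ignore_attr = TRUE)

  perfect <- precisionRecallFscore(positives(truth), truth)
  expect_equal(unname(perfect), c(1, 1, 1), ignore_attr = TRUE)

  none <- precisionRecallFscore(character(0), truth)
  expect_equal(unname(none), c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(none, "no_predictions"))
})

test_that("permutation p-values are extreme for signal, modest under null", {
  truth <- GroundTruth(paste0("p", 1:8), paste0("n", 1:40))
  folds <- makeFolds(truth, k = 4, seed = 5)
  perm <- permutationSignificance(sepFeatures(truth), truth, folds,
                                  B = 99, seed = 6)
  expect_equal(unname(perm$p["aupr"]), 0.01)   # observed beats all 99 nulls
  expect_equal(dim(perm$null), c(99, 4))

  noise <- FeatureMatrix(
    matrix(withSeed(8, rnorm(48)), ncol = 1,
           dimnames = list(labeledGenes(truth), "f1")), "noise")
  permNull <- permutationSignificance(noise, truth, folds, B = 99, seed = 9)
  expect_gt(unname(permNull$p["aupr"]), 0.05)
  expect_error(permutationSignificance(noise, truth, folds, B = 10), "B")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  withSeed(21, {
    for (rep in 1:10) {
      p <- runif(sample(3:30, 1))
      expect_equal(bhAdjust(p), bhStepUpOracle(p), tolerance = 1e-12)
    }
  })
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("best-model selection uses AUPR then F-score then id", {
  mk <- function(id, aupr, f) {
    new("PredictionOutcome", modelId = id,
        scores = c(g1 = 0.6, g2 = 0.4), labels = c(g1 = TRUE, g2 = FALSE),
        folds = c(g1 = 0L, g2 = 1L),
        perFold = data.frame(), threshold = 0.5, flags = list(),
        summary = c(aupr = aupr, precision = 0.5, recall = 0.5, fscore = f))
  }
  expect_equal(selectBestModel(list(mk("m1", 0.3, 0.4), mk("m2", 0.5, 0.4),
                                    mk("m3", 0.4, 0.4))), "m2")
  expect_equal(selectBestModel(list(mk("m1", 0.5, 0.4), mk("m2", 0.5, 0.6))),
               "m2")
  expect_equal(selectBestModel(list(mk("mB", 0.5, 0.4), mk("mA", 0.5, 0.4))),
               "mA")
  expect_equal(selectBestModel(list(mk("only", 0.2, 0.2))), "only")
})
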