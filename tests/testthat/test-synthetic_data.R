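# The synthetic-study generator: network construction, planted aging
# module, expression trends, gene sets and the on-disk bundle.

test_that("scale-free network has exact size and is reproducibly connected", {
  cfg <- studyConfig(nGenes = 100, m = 3, seed = 4)
  net <- generateNetwork(cfg)
  expect_equal(igraph::vcount(net), 100)
  expect_equal(igraph::ecount(net), 3 * 97)
  expect_identical(igraph::as_edgelist(net),
                   igraph::as_edgelist(generateNetwork(cfg)))
  for (s in 1:10) {
    cfgS <- studyConfig(nGenes = sample(20:200, 1), m = sample(1:4, 1),
                        seed = s)
    expect_true(igraph::is_connected(generateNetwork(cfgS)))
  }
})

test_that("planted aging genes have the right counts and cluster together", {
  cfg <- studyConfig(nGenes = 100, agingFraction = 0.06,
                     hiddenFraction = 0.5, seed = 9)
  net <- generateNetwork(cfg)
  pl <- plantAgingGenes(net, cfg)
  expect_length(pl$planted, 6)
  expect_length(pl$hidden, 3)
  expect_true(all(pl$hidden %in% pl$planted))
  expect_setequal(unique(pl$beta), c(-1, 1))

  # planted genes form at least one connected cluster of size >= 3
  for (s in 1:20) {
    cfgS <- studyConfig(seed = s)
    netS <- generateNetwork(cfgS)
    plS <- plantAgingGenes(netS, cfgS)
    sub <- igraph::induced_subgraph(netS, plS$planted)
    expect_gte(max(igraph::components(sub)$csize), 3)
  }

  expect_error(plantAgingGenes(net, studyConfig(nGenes = 100,
                                                agingFraction = 0.004)),
               "< 1")
})

test_that("expression trends follow the planted direction", {
  # s = 0: per-gene sample means stay near the age-independent baseline
  cfg0 <- studyConfig(nGenes = 60, samplesPerAge = 20, signalStrength = 0,
                      seed = 3)
  net <- generateNetwork(cfg0)
  pl <- plantAgingGenes(net, cfg0)
  study <- generateExpression(net, pl, cfg0)
  m <- aggregateByAge(study)
  # multiplicative lognormal noise: per-age mean of mu*exp(N(0, sd)) has
  # sd approximately mu * noiseSd / sqrt(samples); allow 4 sigma
  relSpread <- apply(m, 1, function(x) diff(range(x)) / mean(x))
  expect_lt(max(relSpread), 2 * 4 * cfg0$noiseSd / sqrt(20))

  # s = 1: fitted slope of per-age means matches beta for >= 95% of
  # planted genes over 20 seeds
  agree <- unlist(lapply(1:20, function(s) {
    cfg <- studyConfig(nGenes = 150, seed = s)
    net <- generateNetwork(cfg)
    pl <- plantAgingGenes(net, cfg)
    m <- aggregateByAge(generateExpression(net, pl, cfg))
    t0 <- seq_len(ncol(m)) - mean(seq_len(ncol(m)))
    slopes <- (m[pl$planted, , drop = FALSE] %*% t0) / sum(t0^2)
    sign(slopes) == pl$beta[pl$planted]
  }))
  expect_gte(mean(agree), 0.95)
})

test_that("counts mode produces non-negative integers deterministically", {
  cfg <- studyConfig(nGenes = 80, mode = "counts", seed = 6)
  net <- generateNetwork(cfg)
  pl <- plantAgingGenes(net, cfg)
  study <- generateExpression(net, pl, cfg)
  v <- exprValues(study)
  expect_true(all(v >= 0))
  expect_true(all(v == round(v)))
  expect_identical(v, exprValues(generateExpression(net, pl, cfg)))
  # a different cohort is a different realization of the same design
  other <- generateExpression(net, pl, cfg, cohort = "B")
  expect_false(identical(v, exprValues(other)))
})

test_that("gene sets contain the planted module plus bounded contamination", {
  cfg <- studyConfig(nGenes = 100, agingFraction = 0.06, seed = 2)
  net <- generateNetwork(cfg)
  pl <- plantAgingGenes(net, cfg)
  sets <- generateGeneSets(pl, igraph::V(net)$name, cfg)
  expect_length(sets, 5)
  aging <- geneSets(sets)$aging_pathway
  expect_length(aging, 6 + ceiling(0.2 * 6))      # 6 planted + 2 contaminants
  expect_true(all(pl$planted %in% aging))

  # random sets contain planted genes only at chance rate: total planted
  # hits over 50 seeds within 4 sigma of the hypergeometric expectation
  hits <- 0; draws <- 0
  for (s in 1:50) {
    cfgS <- studyConfig(nGenes = 100, agingFraction = 0.06, seed = s)
    netS <- generateNetwork(cfgS)
    plS <- plantAgingGenes(netS, cfgS)
    setsS <- geneSets(generateGeneSets(plS, igraph::V(netS)$name, cfgS))
    for (nm in paste0("random_set_", 1:4)) {
      hits <- hits + length(intersect(setsS[[nm]], plS$planted))
      draws <- draws + length(setsS[[nm]])
    }
  }
  p <- 6 / 100
  expect_lt(abs(hits - draws * p), 4 * sqrt(draws * p * (1 - p)))
})

test_that("the study bundle writes and re-reads consistently", {
  cfg <- studyConfig(nGenes = 60, samplesPerAge = 2, seed = 8)
  dir <- tempfile("bundle")
  bundle <- generateStudy(cfg, dir)
  expect_true(all(file.exists(unlist(bundle$paths))))

  net <- largestComponent(readEdgeList(bundle$paths$network))
  expect_equal(igraph::vcount(net), igraph::vcount(bundle$network))
  expect_equal(igraph::ecount(net), igraph::ecount(bundle$network))

  study <- readExpression(bundle$paths$expression, bundle$paths$samples)
  expect_equal(exprValues(study), exprValues(bundle$study),
               tolerance = 1e-10)

  visible <- readGeneList(bundle$paths$positives)
  expect_length(visible,
                length(bundle$planting$planted) -
                  length(bundle$planting$hidden))
  expect_false(any(bundle$planting$hidden %in% visible))

  sets <- readGmt(bundle$paths$gmt)
  expect_equal(lapply(geneSets(sets), sort),
               lapply(geneSets(bundle$geneSets), sort))

  manifest <- jsonlite::read_json(bundle$paths$manifest)
  expect_equal(manifest$config$nGenes, 60)
  expect_equal(manifest$seed, 8)

  # exclusion lists never contain visible positives
  for (p in bundle$paths$exclusions) {
    expect_length(intersect(readGeneList(p), visible), 0)
  }
})
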