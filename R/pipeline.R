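## End-to-end orchestration: for each (expression, network) combination,
## infer the dynamic subnetwork, compute the nine features, cross-validate
## the nine predictive models and pick the best by AUPR; then compare
## predictions across combinations and run the gene-group enrichment.
## Composed exclusively of the exported stage functions; deterministic
## under a fixed configuration.

#' Pipeline run configuration
#'
#' @param combinations named list; each element a list with `network` (an
#'   [igraph::igraph] or an edge-list TSV path) and `expression` (an
#'   [ExpressionStudy-class] or `list(matrix =, meta =)` TSV paths).
#' @param positives curated positive gene list (character vector or path to
#'   a one-gene-per-line file).
#' @param exclusions list of exclusion gene lists (character vectors or
#'   paths).
#' @param geneSets optional [GeneSetCollection-class] or GMT path for the
#'   enrichment stage.
#' @param propagation a [propagationConfig()].
#' @param scheme snapshot normalization scheme (see [normalizeSnapshots()]).
#' @param alignPolicy missing-gene policy (see [alignToNetwork()]).
#' @param theta sparsification percentage for binary-graph features.
#' @param classifier a [classifierConfig()].
#' @param k number of cross-validation folds.
#' @param features feature definition ids to evaluate as predictive models.
#' @param permutations permutations B for best-model significance (0 =
#'   skip).
#' @param masterSeed master seed; per-stage seeds are derived with
#'   [stableSeed()] so adding a combination never perturbs the others.
#' @param outDir optional directory for TSV/JSON stage outputs.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(combinations, positives, exclusions = list(),
                      geneSets = NULL,
                      propagation = propagationConfig(),
                      scheme = "per_snapshot_sum",
                      alignPolicy = "zero", theta = 25,
                      classifier = classifierConfig(), k = 5,
                      features = featureRegistry(), permutations = 0,
                      masterSeed = 1, outDir = NULL) {
  stopifnot(length(combinations) >= 1, !is.null(names(combinations)))
  structure(list(combinations = combinations, positives = positives,
                 exclusions = exclusions, geneSets = geneSets,
                 propagation = propagation, scheme = scheme,
                 alignPolicy = alignPolicy, theta = theta,
                 classifier = classifier, k = k, features = features,
                 permutations = permutations, masterSeed = masterSeed,
                 outDir = outDir),
            class = "RunConfig")
}

.loadNetwork <- function(x) {
  if (is.character(x)) x <- readEdgeList(x)
  largestComponent(x)
}

.loadStudy <- function(x) {
  if (is(x, "ExpressionStudy")) return(x)
  readExpression(x$matrix, x$meta, mode = x$mode %||% "intensity")
}

.loadGenes <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    readGeneList(x)
  } else {
    as.character(x)
  }
}

# one combination: expression + network -> best CV outcome
.runCombination <- function(name, combo, truth, folds, cfg) {
  net <- .loadNetwork(combo$network)
  study <- .loadStudy(combo$expression)
  if (exprMode(study) == "counts") study <- tmmNormalize(study)
  means <- aggregateByAge(study)
  profiles <- alignToNetwork(means, net, policy = cfg$alignPolicy)
  snaps <- inferSnapshots(net, profiles, cfg$propagation)
  norm <- normalizeSnapshots(snaps, scheme = cfg$scheme)
  dyn <- buildDynamicSubnetwork(norm)
  outcomes <- lapply(cfg$features, function(fid) {
    fm <- computeFeatureMatrix(dyn, fid, theta = cfg$theta)
    trainPredictCv(fm, truth, folds, cfg$classifier)
  })
  names(outcomes) <- cfg$features
  bestId <- selectBestModel(outcomes)
  perm <- NULL
  if (cfg$permutations > 0) {
    fm <- computeFeatureMatrix(dyn, bestId, theta = cfg$theta)
    perm <- permutationSignificance(
      fm, truth, folds, cfg$classifier, B = cfg$permutations,
      seed = stableSeed(cfg$masterSeed, "permutation", name),
      observed = outcomes[[bestId]])
  }
  list(name = name, network = net, dynamic = dyn, outcomes = outcomes,
       bestModel = bestId, best = outcomes[[bestId]],
       permutation = perm)
}

#' Run the full experiment
#'
#' Builds the ground-truth labels on the common gene universe of all
#' combination networks, fixes one stratified fold assignment shared by
#' every model and combination, runs each combination through
#' propagation, dynamic-subnetwork inference, feature computation and
#' cross-validated prediction, selects each combination's best model by
#' AUPR, and (for two or more combinations) compares true-positive and
#' novel prediction sets, assigns the four gene groups and computes the
#' enrichment table.
#'
#' @param cfg a [runConfig()].
#' @return A report list with elements `truth`, `folds`, `combinations`
#'   (per-combination results), `bestModels`, `predictions`, `comparison`,
#'   `groups`, `enrichment` and `manifest`.
#' @export
runAll <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  nets <- lapply(cfg$combinations, function(cb) .loadNetwork(cb$network))
  universe <- commonUniverse(nets)
  truth <- buildLabels(universe, .loadGenes(cfg$positives),
                       lapply(cfg$exclusions, .loadGenes))
  folds <- makeFolds(truth, k = cfg$k,
                     seed = stableSeed(cfg$masterSeed, "folds"))

  results <- lapply(names(cfg$combinations), function(nm) {
    .runCombination(nm, cfg$combinations[[nm]], truth, folds, cfg)
  })
  names(results) <- names(cfg$combinations)

  predictions <- lapply(results, function(r) predictedGenes(r$best))
  comparison <- NULL
  groups <- NULL
  enrichment <- NULL
  if (length(predictions) >= 2) {
    comparison <- pairwiseOverlaps(predictions, truth)
  }
  groups <- assignGroups(predictions, truth)
  if (!is.null(cfg$geneSets)) {
    sets <- if (is.character(cfg$geneSets)) {
      readGmt(cfg$geneSets)
    } else {
      cfg$geneSets
    }
    enrichment <- enrichmentTable(groups, sets)
  }

  manifest <- list(
    masterSeed = cfg$masterSeed,
    foldsSeed = stableSeed(cfg$masterSeed, "folds"),
    k = cfg$k, scheme = cfg$scheme, theta = cfg$theta,
    alignPolicy = cfg$alignPolicy,
    restart = cfg$propagation$restart,
    permutations = cfg$permutations,
    features = cfg$features,
    combinations = names(cfg$combinations),
    labelCounts = labelCounts(truth),
    bestModels = lapply(results, `[[`, "bestModel"))

  report <- list(truth = truth, folds = folds, combinations = results,
                 bestModels = vapply(results, `[[`, "", "bestModel"),
                 predictions = predictions, comparison = comparison,
                 groups = groups, enrichment = enrichment,
                 manifest = manifest)
  if (!is.null(cfg$outDir)) .writeReport(report, cfg)
  report
}

# TSV/JSON stage outputs under cfg$outDir
.writeReport <- function(report, cfg) {
  dir <- cfg$outDir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLabels(report$truth, file.path(dir, "labels.tsv"))
  for (nm in names(report$combinations)) {
    r <- report$combinations[[nm]]
    writeSnapshots(r$dynamic, file.path(dir, paste0(nm, "_dynamic.tsv")))
    metrics <- lapply(r$outcomes, function(o) as.list(cvMetrics(o)))
    jsonlite::write_json(
      list(bestModel = r$bestModel, metrics = metrics,
           permutationP = if (!is.null(r$permutation)) {
             as.list(r$permutation$p)
           } else {
             NULL
           }),
      file.path(dir, paste0(nm, "_metrics.json")),
      auto_unbox = TRUE, digits = NA)
    write.table(
      data.frame(gene = names(predictionScores(r$best)),
                 score = predictionScores(r$best),
                 predicted = as.integer(
                   names(predictionScores(r$best)) %in%
                     predictedGenes(r$best)),
                 fold = r$best@folds),
      file.path(dir, paste0(nm, "_predictions.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$comparison)) {
    write.table(report$comparison$overlaps,
                file.path(dir, "overlaps.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(report$comparison$uniqueCounts,
                file.path(dir, "unique_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$enrichment)) {
    write.table(report$enrichment, file.path(dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
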