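## Accessors and show() methods. Slots are never touched outside the package.

#' @describeIn ExpressionStudy expression matrix (genes x samples).
#' @param x an object of the documented class.
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "ExpressionStudy"))
  SummarizedExperiment::assay(x, "exprs")
}

#' @describeIn ExpressionStudy per-sample age (numeric) or age-group factor.
#' @export
sampleAges <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("age" %in% colnames(cd)) cd$age else cd$age_group
}

#' @describeIn ExpressionStudy `"numeric"` (ages in years) or `"group"`.
#' @export
ageMode <- function(x) {
  if ("age" %in% colnames(SummarizedExperiment::colData(x))) {
    "numeric"
  } else {
    "group"
  }
}

#' @describeIn ExpressionStudy `"intensity"` or `"counts"`.
#' @export
exprMode <- function(x) S4Vectors::metadata(x)$mode

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  mode:", exprMode(object), "| age:", ageMode(object), "\n")
  a <- sampleAges(object)
  if (is.numeric(a)) {
    cat("  ages:", paste(range(a), collapse = "-"), "years,",
        length(unique(a)), "distinct\n")
  } else {
    cat("  groups:", paste(levels(a), collapse = ", "), "\n")
  }
})

#' @describeIn AgeProfiles gene x age score matrix.
#' @param x an object of the documented class.
#' @export
profileScores <- function(x) { stopifnot(is(x, "AgeProfiles")); x@scores }

#' @describeIn AgeProfiles ordered age labels.
#' @export
profileAges <- function(x) { stopifnot(is(x, "AgeProfiles")); x@ages }

#' @describeIn AgeProfiles gene identifiers (network node set).
#' @export
profileGenes <- function(x) rownames(profileScores(x))

setMethod("show", "AgeProfiles", function(object) {
  cat("AgeProfiles:", nrow(object@scores), "genes x",
      length(object@ages), "ages (", paste(object@ages, collapse = ", "),
      ")\n")
})

#' @describeIn SnapshotSeries base edge table (two-column gene matrix).
#' @param x an object of the documented class.
#' @export
snapshotEdges <- function(x) x@edges

#' @describeIn SnapshotSeries edge x age weight matrix.
#' @export
snapshotWeights <- function(x) { stopifnot(is(x, "SnapshotSeries")); x@weights }

#' @describeIn SnapshotSeries ordered age labels.
#' @export
snapshotAges <- function(x) { stopifnot(is(x, "SnapshotSeries")); x@ages }

#' @describeIn SnapshotSeries normalization scheme tag (`""` = raw fluxes).
#' @export
normScheme <- function(x) x@scheme

setMethod("show", "SnapshotSeries", function(object) {
  cat("SnapshotSeries:", nrow(object@edges), "edges x",
      ncol(object@weights), "snapshots",
      if (nzchar(object@scheme)) paste0("[", object@scheme, "]") else
        "[unnormalized]", "\n")
})

#' @describeIn DynamicSubnetwork edge x interval differential weight matrix.
#' @param x an object of the documented class.
#' @export
diffWeights <- function(x) { stopifnot(is(x, "DynamicSubnetwork")); x@diffWeights }

#' @describeIn DynamicSubnetwork consecutive-age interval labels.
#' @export
diffIntervals <- function(x) { stopifnot(is(x, "DynamicSubnetwork")); x@intervals }

#' @describeIn DynamicSubnetwork number of input snapshots x (intervals + 1).
#' @export
nSnapshots <- function(x) {
  if (is(x, "DynamicSubnetwork")) return(ncol(x@diffWeights) + 1L)
  ncol(snapshotWeights(x))
}

setMethod("show", "DynamicSubnetwork", function(object) {
  cat("DynamicSubnetwork:", nrow(object@edges), "edges,",
      ncol(object@diffWeights), "differential snapshots (x =",
      ncol(object@diffWeights) + 1L, "), scheme:", object@scheme, "\n")
})

#' @describeIn GroundTruth aging-related (positive) gene ids.
#' @param x an object of the documented class.
#' @export
positives <- function(x) { stopifnot(is(x, "GroundTruth")); x@positives }

#' @describeIn GroundTruth non-aging-related (negative) gene ids.
#' @export
negatives <- function(x) { stopifnot(is(x, "GroundTruth")); x@negatives }

#' @describeIn GroundTruth construction counts (n_universe, n_positives,
#'   n_candidates, n_negatives, n_labeled).
#' @export
labelCounts <- function(x) { stopifnot(is(x, "GroundTruth")); x@counts }

#' @describeIn GroundTruth all labeled genes, sorted.
#' @export
labeledGenes <- function(x) sort(c(positives(x), negatives(x)))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@positives), "aging-related,",
      length(object@negatives), "non-aging-related genes\n")
})

#' @describeIn GeneSetCollection named list of member-gene vectors.
#' @param x an object of the documented class.
#' @export
geneSets <- function(x) { stopifnot(is(x, "GeneSetCollection")); x@sets }

#' @describeIn GeneSetCollection set names.
#' @export
geneSetNames <- function(x) names(geneSets(x))

#' @describeIn GeneSetCollection set descriptions (named by set).
#' @export
setDescriptions <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@descriptions
}

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets, sizes",
      paste(vapply(object@sets, length, 1L), collapse = ", "), "\n")
})

#' @describeIn FeatureMatrix gene x dimension value matrix.
#' @param x an object of the documented class.
#' @export
featureValues <- function(x) { stopifnot(is(x, "FeatureMatrix")); x@values }

#' @describeIn FeatureMatrix feature definition id.
#' @export
featureId <- function(x) { stopifnot(is(x, "FeatureMatrix")); x@featureId }

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix '", object@featureId, "': ", nrow(object@values),
      " genes x ", ncol(object@values), " dims\n", sep = "")
})

#' @describeIn FoldAssignment named integer vector gene -> fold id (0-based).
#' @param x an object of the documented class.
#' @export
foldIds <- function(x) { stopifnot(is(x, "FoldAssignment")); x@folds }

#' @describeIn FoldAssignment number of folds.
#' @export
nFolds <- function(x) { stopifnot(is(x, "FoldAssignment")); x@k }

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment:", length(object@folds), "genes in", object@k,
      "folds (seed", object@seed, ")\n")
})

#' @describeIn PredictionOutcome out-of-fold scores, named by gene.
#' @param x an object of the documented class.
#' @export
predictionScores <- function(x) { stopifnot(is(x, "PredictionOutcome")); x@scores }

#' @describeIn PredictionOutcome genes predicted aging-related
#'   (score >= threshold), sorted.
#' @export
predictedGenes <- function(x) {
  stopifnot(is(x, "PredictionOutcome"))
  sort(names(x@labels)[x@labels])
}

#' @describeIn PredictionOutcome per-fold metric table.
#' @export
foldMetrics <- function(x) { stopifnot(is(x, "PredictionOutcome")); x@perFold }

#' @describeIn PredictionOutcome fold-averaged aupr/precision/recall/fscore.
#' @export
cvMetrics <- function(x) { stopifnot(is(x, "PredictionOutcome")); x@summary }

#' @describeIn PredictionOutcome model (feature definition) id.
#' @export
modelId <- function(x) { stopifnot(is(x, "PredictionOutcome")); x@modelId }

setMethod("show", "PredictionOutcome", function(object) {
  m <- object@summary
  cat("PredictionOutcome '", object@modelId, "': ",
      length(predictedGenes(object)), " genes predicted aging-related\n",
      sprintf("  AUPR %.3f | precision %.3f | recall %.3f | F %.3f\n",
              m["aupr"], m["precision"], m["recall"], m["fscore"]),
      sep = "")
})

#' @describeIn GeneGroups named list of the four groups.
#' @param x an object of the documented class.
#' @export
geneGroupList <- function(x) {
  stopifnot(is(x, "GeneGroups"))
  list(PredictedAging = x@predictedAging,
       PredictedNonAging = x@predictedNonAging,
       NotPredictedAging = x@notPredictedAging,
       NotPredictedNonAging = x@notPredictedNonAging)
}

setMethod("show", "GeneGroups", function(object) {
  n <- vapply(geneGroupList(object), length, 1L)
  cat("GeneGroups:", paste(names(n), n, sep = "=", collapse = ", "), "\n")
})
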