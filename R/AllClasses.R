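## Central S4 containers. Networks themselves are igraph objects (undirected,
## simple, vertex attribute "name" = gene id); everything layered on top of a
## network carries the edge table explicitly so objects remain self-contained.

#' ExpressionStudy: gene x sample expression with per-sample age
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with one assay
#' (`"exprs"`, non-negative), a `colData` column `age` (numeric years) or
#' `age_group` (factor whose level order is the age order), and a metadata
#' flag `mode` (`"intensity"` or `"counts"`).
#'
#' @aliases ExpressionStudy-class
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

.validExpressionStudy <- function(object) {
  msg <- character()
  v <- SummarizedExperiment::assay(object, 1)
  if (is.null(rownames(v)) || anyDuplicated(rownames(v))) {
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    msg <- c(msg, "expression values must be finite and non-negative")
  }
  cd <- SummarizedExperiment::colData(object)
  hasAge <- "age" %in% colnames(cd)
  hasGrp <- "age_group" %in% colnames(cd)
  if (hasAge == hasGrp) {
    msg <- c(msg, "colData must carry exactly one of 'age' or 'age_group'")
  } else if (hasAge && any(!is.finite(cd$age))) {
    msg <- c(msg, "every sample needs a finite numeric age")
  } else if (hasGrp && any(is.na(cd$age_group))) {
    msg <- c(msg, "every sample needs an age-group label")
  }
  mode <- S4Vectors::metadata(object)$mode
  if (!identical(mode, "intensity") && !identical(mode, "counts")) {
    msg <- c(msg, "metadata()$mode must be 'intensity' or 'counts'")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ExpressionStudy", .validExpressionStudy)

#' Construct an ExpressionStudy
#'
#' @param values gene x sample matrix of non-negative expression values with
#'   gene ids as rownames and sample ids as colnames.
#' @param age numeric per-sample age in years (mutually exclusive with
#'   `ageGroup`).
#' @param ageGroup character/factor per-sample age-group label; if character,
#'   level order defaults to first appearance sorted by `groupOrder`.
#' @param groupOrder optional explicit ordering of the age-group labels.
#' @param mode `"intensity"` (default) or `"counts"`.
#' @return An [ExpressionStudy-class] object.
#' @export
ExpressionStudy <- function(values, age = NULL, ageGroup = NULL,
                            groupOrder = NULL,
                            mode = c("intensity", "counts")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  if (!is.null(age) && !is.null(ageGroup)) {
    stop("supply either 'age' or 'ageGroup', not both")
  }
  if (!is.null(age)) {
    stopifnot(length(age) == ncol(values))
    cd <- S4Vectors::DataFrame(age = as.numeric(age),
                               row.names = colnames(values))
  } else if (!is.null(ageGroup)) {
    stopifnot(length(ageGroup) == ncol(values))
    if (!is.factor(ageGroup)) {
      lev <- groupOrder %||% sort(unique(as.character(ageGroup)))
      ageGroup <- factor(as.character(ageGroup), levels = lev)
    }
    cd <- S4Vectors::DataFrame(age_group = ageGroup,
                               row.names = colnames(values))
  } else {
    stop("one of 'age' or 'ageGroup' is required")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd,
    metadata = list(mode = mode)
  )
  new("ExpressionStudy", se)
}

#' AgeProfiles: per-age node scores over a fixed network
#'
#' Gene x age matrix of aggregated non-negative scores used to bias the
#' random walk; the gene set equals the node set of the network the profiles
#' were aligned to.
#'
#' @aliases AgeProfiles-class
#' @export
setClass("AgeProfiles",
  representation(scores = "matrix", ages = "character"))

setValidity("AgeProfiles", function(object) {
  msg <- character()
  s <- object@scores
  if (is.null(rownames(s)) || anyDuplicated(rownames(s))) {
    msg <- c(msg, "scores need unique gene rownames")
  }
  if (any(!is.finite(s)) || any(s < 0)) {
    msg <- c(msg, "scores must be finite and non-negative")
  }
  if (length(object@ages) != ncol(s)) {
    msg <- c(msg, "one age label per score column required")
  }
  if (ncol(s) > 0 && any(colSums(s) <= 0)) {
    msg <- c(msg, "every age needs at least one positive score")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname AgeProfiles-class
#' @param scores gene x age non-negative matrix with gene rownames.
#' @param ages age labels (defaults to the score column names).
#' @export
AgeProfiles <- function(scores, ages = colnames(scores)) {
  scores <- as.matrix(scores)
  ages <- as.character(ages)
  colnames(scores) <- ages
  new("AgeProfiles", scores = scores, ages = ages)
}

#' SnapshotSeries: per-age weighted snapshots over one base network
#'
#' Holds the base edge table (two-column character matrix of gene pairs) and
#' one non-negative weight column per age, in ascending age order. A single
#' snapshot is a one-column series. `scheme` is `""` until normalization.
#'
#' @aliases SnapshotSeries-class
#' @export
setClass("SnapshotSeries",
  representation(edges = "matrix", weights = "matrix", ages = "character",
                 scheme = "character"))

setValidity("SnapshotSeries", function(object) {
  msg <- character()
  e <- object@edges
  w <- object@weights
  if (!is.character(e) || ncol(e) != 2) {
    msg <- c(msg, "edges must be a two-column character matrix")
  }
  if (nrow(e) != nrow(w)) msg <- c(msg, "one weight row per edge required")
  if (any(!is.finite(w)) || any(w < 0)) {
    msg <- c(msg, "snapshot weights must be finite and non-negative")
  }
  if (length(object@ages) != ncol(w)) {
    msg <- c(msg, "one age label per weight column required")
  }
  if (length(object@scheme) != 1) msg <- c(msg, "scheme must be length 1")
  if (length(msg)) msg else TRUE
})

#' @rdname SnapshotSeries-class
#' @param edges two-column character matrix of gene pairs.
#' @param weights edge x age non-negative weight matrix.
#' @param ages ordered age labels, one per weight column.
#' @param scheme normalization scheme tag (default `""` = unnormalized).
#' @export
SnapshotSeries <- function(edges, weights, ages, scheme = "") {
  weights <- as.matrix(weights)
  colnames(weights) <- ages
  new("SnapshotSeries", edges = as.matrix(edges), weights = weights,
      ages = as.character(ages), scheme = scheme)
}

#' DynamicSubnetwork: ordered differential snapshots
#'
#' For x input snapshots, x - 1 differential weight columns, each the
#' relative weight change between consecutive normalized snapshots scaled to
#' `[-100, 100]`.
#'
#' @aliases DynamicSubnetwork-class
#' @export
setClass("DynamicSubnetwork",
  representation(edges = "matrix", diffWeights = "matrix",
                 intervals = "character", scheme = "character"))

setValidity("DynamicSubnetwork", function(object) {
  msg <- character()
  w <- object@diffWeights
  if (nrow(object@edges) != nrow(w)) {
    msg <- c(msg, "one differential weight row per edge required")
  }
  if (any(!is.finite(w)) || any(w < -100 - 1e-9) || any(w > 100 + 1e-9)) {
    msg <- c(msg, "differential weights must lie in [-100, 100]")
  }
  if (length(object@intervals) != ncol(w)) {
    msg <- c(msg, "one interval label per differential snapshot required")
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: aging / non-aging gene labels
#'
#' @aliases GroundTruth-class
#' @export
setClass("GroundTruth",
  representation(positives = "character", negatives = "character",
                 counts = "list"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (length(intersect(object@positives, object@negatives))) {
    msg <- c(msg, "positives and negatives must be disjoint")
  }
  if (anyDuplicated(object@positives) || anyDuplicated(object@negatives)) {
    msg <- c(msg, "label sets must not contain duplicates")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GroundTruth-class
#' @param positives,negatives disjoint character vectors of gene ids.
#' @param counts optional list of construction counts (see [buildLabels()]).
#' @export
GroundTruth <- function(positives, negatives, counts = list()) {
  new("GroundTruth", positives = sort(unique(as.character(positives))),
      negatives = sort(unique(as.character(negatives))), counts = counts)
}

#' GeneSetCollection: named gene sets with descriptions
#'
#' @aliases GeneSetCollection-class
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (length(object@sets) && (is.null(nm) || anyDuplicated(nm) ||
                              any(!nzchar(nm)))) {
    msg <- c(msg, "set names must be unique and non-empty")
  }
  if (any(!vapply(object@sets, length, 1L))) {
    msg <- c(msg, "gene sets must be non-empty")
  }
  if (length(object@descriptions) != length(object@sets)) {
    msg <- c(msg, "one description per set required")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets named list of character vectors of member genes.
#' @param descriptions optional per-set description strings.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  new("GeneSetCollection", sets = sets,
      descriptions = as.character(descriptions))
}

#' FeatureMatrix: per-gene dynamic network feature vectors
#'
#' @aliases FeatureMatrix-class
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", featureId = "character",
                 provenance = "list"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (any(!is.finite(object@values))) {
    msg <- c(msg, "feature values must be finite")
  }
  if (is.null(rownames(object@values))) {
    msg <- c(msg, "feature rows must be named by gene")
  }
  if (length(object@featureId) != 1) {
    msg <- c(msg, "featureId must be a single id")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureMatrix-class
#' @param values gene x dimension matrix with gene rownames.
#' @param featureId feature definition id.
#' @param provenance free-form provenance list (parameters, subnetwork id).
#' @export
FeatureMatrix <- function(values, featureId, provenance = list()) {
  new("FeatureMatrix", values = as.matrix(values), featureId = featureId,
      provenance = provenance)
}

#' FoldAssignment: stratified cross-validation fold ids
#'
#' @aliases FoldAssignment-class
#' @export
setClass("FoldAssignment",
  representation(folds = "integer", k = "integer", seed = "integer"))

setValidity("FoldAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@folds))) msg <- c(msg, "folds must be gene-named")
  if (length(object@folds) &&
      (min(object@folds) < 0L || max(object@folds) >= object@k)) {
    msg <- c(msg, "fold ids must lie in {0..k-1}")
  }
  if (length(msg)) msg else TRUE
})

#' PredictionOutcome: out-of-fold scores, labels and CV metrics for one model
#'
#' @aliases PredictionOutcome-class
#' @export
setClass("PredictionOutcome",
  representation(modelId = "character", scores = "numeric",
                 labels = "logical", folds = "integer",
                 perFold = "data.frame", summary = "numeric",
                 threshold = "numeric", flags = "list"))

setValidity("PredictionOutcome", function(object) {
  msg <- character()
  need <- c("aupr", "precision", "recall", "fscore")
  if (!all(need %in% names(object@summary))) {
    msg <- c(msg, "summary must carry aupr, precision, recall, fscore")
  } else {
    s <- object@summary[need]
    if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
      msg <- c(msg, "summary metrics must lie in [0, 1]")
    }
  }
  if (!identical(names(object@scores), names(object@labels))) {
    msg <- c(msg, "scores and labels must cover the same genes")
  }
  if (length(msg)) msg else TRUE
})

#' GeneGroups: four-way split of labeled genes
#'
#' Predicted x ground-truth label combinations (predicted by at least one
#' subnetwork vs by none).
#'
#' @aliases GeneGroups-class
#' @export
setClass("GeneGroups",
  representation(predictedAging = "character",
                 predictedNonAging = "character",
                 notPredictedAging = "character",
                 notPredictedNonAging = "character"))

setValidity("GeneGroups", function(object) {
  g <- geneGroupList(object)
  all <- unlist(g, use.names = FALSE)
  if (anyDuplicated(all)) "gene groups must be pairwise disjoint" else TRUE
})
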