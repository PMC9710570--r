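## Cross-subnetwork prediction comparison and gene-group enrichment:
## Jaccard overlaps of true-positive and novel prediction sets with
## one-sided hypergeometric significance, the four-way gene grouping by
## predicted x ground-truth label, and group x gene-set enrichment tables.
## BH adjustment is applied within each test family.

#' Genes present in every network
#'
#' @param nets list of [igraph::igraph] networks.
#' @return Sorted intersection of the node sets.
#' @export
commonUniverse <- function(nets) {
  stopifnot(length(nets) >= 1)
  u <- Reduce(intersect, lapply(nets, function(n) igraph::V(n)$name))
  if (!length(u)) stop("networks share no genes", call. = FALSE)
  sort(u)
}

#' Split predictions into true positives and novel predictions
#'
#' True positives are predicted genes labeled aging-related in the ground
#' truth; novel predictions are predicted genes currently labeled
#' non-aging-related.
#'
#' @param predicted character vector of predicted aging-related genes; must
#'   be a subset of the labeled genes.
#' @param truth a [GroundTruth-class].
#' @return List with `truePositives` and `novel`.
#' @export
splitTpNovel <- function(predicted, truth) {
  outside <- setdiff(predicted, labeledGenes(truth))
  if (length(outside)) {
    stop("predicted gene outside the labeled set: ", outside[1],
         call. = FALSE)
  }
  list(truePositives = sort(intersect(predicted, positives(truth))),
       novel = sort(intersect(predicted, negatives(truth))))
}

#' Jaccard index of two gene sets
#'
#' @param a,b character vectors with non-empty union.
#' @return `|intersection| / |union|`.
#' @export
jaccardIndex <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) stop("Jaccard undefined for two empty sets",
                       call. = FALSE)
  length(intersect(a, b)) / length(u)
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing an overlap at least as large as the one seen
#' when `sizeB` genes are drawn without replacement from a universe
#' containing `sizeA` marked genes: `P(X >= overlap)`. Symmetric in
#' `sizeA` and `sizeB`.
#'
#' @param sizeA,sizeB sizes of the two sets.
#' @param overlap observed intersection size.
#' @param universeSize size of the common universe.
#' @return p-value in `[0, 1]`.
#' @export
hypergeomOverlapP <- function(sizeA, sizeB, overlap, universeSize) {
  if (overlap > min(sizeA, sizeB) || sizeA > universeSize ||
      sizeB > universeSize || overlap < 0) {
    stop("inconsistent overlap configuration", call. = FALSE)
  }
  phyper(overlap - 1, sizeA, universeSize - sizeA, sizeB,
         lower.tail = FALSE)
}

#' Pairwise overlaps of per-subnetwork prediction sets
#'
#' For each unordered pair of subnetworks, and separately for their
#' true-positive and novel prediction sets, reports the Jaccard index, the
#' raw overlap count and the hypergeometric p-value, BH-adjusted within
#' each (true-positive / novel) family. Also counts, per subnetwork, the
#' predictions made by it and no other subnetwork.
#'
#' @param predictions named list: subnetwork id -> predicted gene set
#'   (subset of the labeled genes).
#' @param truth a [GroundTruth-class].
#' @param universe genes the overlap test draws from; defaults to the
#'   labeled genes.
#' @return List with `overlaps` (data frame of pair records) and
#'   `uniqueCounts` (data frame per subnetwork and prediction type).
#' @export
pairwiseOverlaps <- function(predictions, truth,
                             universe = labeledGenes(truth)) {
  stopifnot(length(predictions) >= 2, !is.null(names(predictions)))
  splits <- lapply(predictions, splitTpNovel, truth = truth)
  types <- c(truePositives = "true_positive", novel = "novel")
  pairs <- combn(names(predictions), 2)
  rows <- list()
  for (tKey in names(types)) {
    sets <- lapply(splits, `[[`, tKey)
    for (j in seq_len(ncol(pairs))) {
      a <- sets[[pairs[1, j]]]
      b <- sets[[pairs[2, j]]]
      ov <- length(intersect(a, b))
      rows[[length(rows) + 1]] <- data.frame(
        type = types[[tKey]], idA = pairs[1, j], idB = pairs[2, j],
        sizeA = length(a), sizeB = length(b), overlap = ov,
        jaccard = if (length(union(a, b))) jaccardIndex(a, b) else NA_real_,
        p = hypergeomOverlapP(length(a), length(b), ov, length(universe)))
    }
  }
  overlaps <- do.call(rbind, rows)
  overlaps$adjP <- NA_real_
  for (tt in unique(overlaps$type)) {
    sel <- overlaps$type == tt
    overlaps$adjP[sel] <- bhAdjust(overlaps$p[sel])
  }
  uniq <- do.call(rbind, lapply(names(types), function(tKey) {
    sets <- lapply(splits, `[[`, tKey)
    data.frame(
      type = types[[tKey]], id = names(sets),
      unique = vapply(names(sets), function(id) {
        others <- unique(unlist(sets[setdiff(names(sets), id)]))
        length(setdiff(sets[[id]], others))
      }, 0L),
      total = lengths(sets), row.names = NULL)
  }))
  list(overlaps = overlaps, uniqueCounts = uniq)
}

#' Four-way gene grouping by predicted and ground-truth label
#'
#' A gene is "Predicted" if at least one subnetwork predicts it as
#' aging-related. The four groups partition the labeled genes.
#'
#' @param predictions named list of predicted gene sets (subsets of the
#'   labeled genes).
#' @param truth a [GroundTruth-class].
#' @return A [GeneGroups-class].
#' @export
assignGroups <- function(predictions, truth) {
  u <- unique(unlist(predictions, use.names = FALSE))
  outside <- setdiff(u, labeledGenes(truth))
  if (length(outside)) {
    stop("predicted gene outside the labeled set: ", outside[1],
         call. = FALSE)
  }
  new("GeneGroups",
      predictedAging = sort(intersect(u, positives(truth))),
      predictedNonAging = sort(intersect(u, negatives(truth))),
      notPredictedAging = sort(setdiff(positives(truth), u)),
      notPredictedNonAging = sort(setdiff(negatives(truth), u)))
}

#' Gene-group x gene-set enrichment table
#'
#' Each gene set is first restricted to the universe (the labeled genes by
#' default); per (group, set) cell the table reports the Jaccard index, the
#' raw overlap count and the upper-tail hypergeometric p-value, BH-adjusted
#' across the full group x set family, plus a significance flag at
#' adjusted p < 0.05.
#'
#' @param groups a [GeneGroups-class].
#' @param sets a [GeneSetCollection-class].
#' @param universe the enrichment universe; defaults to the union of the
#'   four groups (the labeled genes).
#' @param alpha significance level for the flag.
#' @return Data frame with one row per (group, set).
#' @export
enrichmentTable <- function(groups, sets,
                            universe = unlist(geneGroupList(groups),
                                              use.names = FALSE),
                            alpha = 0.05) {
  grp <- geneGroupList(groups)
  restricted <- lapply(geneSets(sets), intersect, y = universe)
  restricted <- restricted[lengths(restricted) > 0]
  if (!length(restricted)) {
    stop("no gene set overlaps the universe", call. = FALSE)
  }
  rows <- list()
  for (gName in names(grp)) {
    for (sName in names(restricted)) {
      g <- intersect(grp[[gName]], universe)
      s <- restricted[[sName]]
      ov <- length(intersect(g, s))
      rows[[length(rows) + 1]] <- data.frame(
        group = gName, set = sName, groupSize = length(g),
        setSize = length(s), overlap = ov,
        jaccard = if (length(union(g, s))) {
          jaccardIndex(g, s)
        } else {
          NA_real_
        },
        p = if (length(g)) {
          hypergeomOverlapP(length(g), length(s), ov, length(universe))
        } else {
          1
        })
    }
  }
  out <- do.call(rbind, rows)
  out$adjP <- bhAdjust(out$p)
  out$significant <- out$adjP < alpha
  out
}
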