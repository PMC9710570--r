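## Expression -> propagation-ready node scores, and ground-truth label
## construction.

#' Average expression per gene per age
#'
#' Assigns to each gene the arithmetic mean expression of all samples at a
#' given age (or age group). Numeric ages are ordered ascending; age groups
#' follow their factor level order.
#'
#' @param study an [ExpressionStudy-class].
#' @return A gene x age matrix with age labels as column names.
#' @export
aggregateByAge <- function(study) {
  v <- exprValues(study)
  a <- sampleAges(study)
  if (is.numeric(a)) {
    ages <- sort(unique(a))
    key <- as.character(a)
    cols <- as.character(ages)
  } else {
    a <- droplevels(a)
    ages <- levels(a)
    if (!all(table(a) > 0)) {
      stop("age group without samples: ",
           ages[which(table(a) == 0)[1]], call. = FALSE)
    }
    key <- as.character(a)
    cols <- ages
  }
  out <- vapply(cols, function(g) {
    rowMeans(v[, key == g, drop = FALSE])
  }, numeric(nrow(v)))
  matrix(out, nrow = nrow(v), dimnames = list(rownames(v), cols))
}

#' Align a gene x age matrix to a network's node set
#'
#' Network genes absent from the expression matrix receive, per age, either
#' an expression value of zero (`policy = "zero"`) or the mean of the
#' lowest-quartile expressed genes at that age (`policy =
#' "background_mean"`, a background-level fill for genes measured as
#' inactive). Matrix genes absent from the network are dropped.
#'
#' @param means gene x age matrix (e.g. from [aggregateByAge()]).
#' @param net [igraph::igraph] network whose nodes define the output genes.
#' @param policy `"zero"` or `"background_mean"`.
#' @return An [AgeProfiles-class] covering exactly the network's nodes.
#' @export
alignToNetwork <- function(means, net, policy = c("zero", "background_mean")) {
  policy <- match.arg(policy)
  nodes <- sort(igraph::V(net)$name)
  common <- intersect(nodes, rownames(means))
  if (!length(common)) {
    stop("no overlap between expression genes and network nodes",
         call. = FALSE)
  }
  out <- matrix(0, length(nodes), ncol(means),
                dimnames = list(nodes, colnames(means)))
  out[common, ] <- means[common, , drop = FALSE]
  missing <- setdiff(nodes, common)
  if (length(missing) && policy == "background_mean") {
    fill <- apply(means[common, , drop = FALSE], 2, function(x) {
      mean(x[x <= quantile(x, 0.25)])
    })
    out[missing, ] <- rep(fill, each = length(missing))
  }
  AgeProfiles(out, colnames(means) %||% as.character(seq_len(ncol(means))))
}

#' Build aging / non-aging ground-truth labels
#'
#' Positives are the curated positive list intersected with the gene
#' universe; candidates are the remaining universe genes; negatives are the
#' candidates minus the union of the exclusion lists (genes appearing in any
#' additional aging dataset are too suspect to serve as confident
#' negatives).
#'
#' @param universe character vector of genes under consideration (e.g. the
#'   common node set of all subnetworks).
#' @param positivesSource curated positive gene list.
#' @param exclusionLists list of character vectors of genes to exclude from
#'   the negatives.
#' @return A [GroundTruth-class] whose [labelCounts()] record `n_universe`,
#'   `n_positives`, `n_candidates`, `n_negatives` and `n_labeled`.
#' @export
#' @examples
#' truth <- buildLabels(letters[1:10], c("a", "b", "z"), list(c("c", "d")))
#' labelCounts(truth)
buildLabels <- function(universe, positivesSource, exclusionLists = list()) {
  universe <- unique(as.character(universe))
  pos <- intersect(unique(as.character(positivesSource)), universe)
  if (!length(pos)) {
    stop("no positive genes present in the universe", call. = FALSE)
  }
  candidates <- setdiff(universe, pos)
  excluded <- unique(unlist(exclusionLists, use.names = FALSE))
  neg <- setdiff(candidates, excluded)
  GroundTruth(pos, neg, counts = list(
    n_universe = length(universe),
    n_positives = length(pos),
    n_candidates = length(candidates),
    n_negatives = length(neg),
    n_labeled = length(pos) + length(neg)))
}
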