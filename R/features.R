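## The nine per-gene dynamic network feature definitions computed from a
## DynamicSubnetwork. Differential weights are signed, so weighted-degree
## features come in signed / positive-channel / negative-channel variants;
## binary-graph features (clustering, closeness, k-core, graphlet orbits)
## are computed on per-snapshot graphs sparsified to the top theta percent
## of absolute differential weight. The registry is pluggable: each
## definition maps an id to a function of the subnetwork.

.baseGenes <- function(dyn) sort(unique(c(dyn@edges)))

# edge endpoint indices into the sorted gene vector
.edgeIndex <- function(dyn, genes = .baseGenes(dyn)) {
  cbind(match(dyn@edges[, 1], genes), match(dyn@edges[, 2], genes))
}

.weightedDegree <- function(w, idx, n) {
  out <- numeric(n)
  agg <- rowsum(c(w, w), c(idx[, 1], idx[, 2]))
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Split a differential snapshot into positive and negative subgraphs
#'
#' The positive subgraph keeps edges with positive differential weight at
#' that weight; the negative subgraph keeps edges with negative weight at
#' its absolute value; zero-weight edges appear in neither. Both graphs
#' contain every base gene as a vertex.
#'
#' @param dyn a [DynamicSubnetwork-class].
#' @param interval differential snapshot index (1 .. x - 1).
#' @return List of two weighted [igraph::igraph]s, `positive` and
#'   `negative`.
#' @export
splitSigned <- function(dyn, interval = 1) {
  w <- diffWeights(dyn)[, interval]
  genes <- .baseGenes(dyn)
  mk <- function(keep, wt) {
    g <- igraph::graph_from_data_frame(
      data.frame(a = dyn@edges[keep, 1], b = dyn@edges[keep, 2],
                 weight = wt),
      directed = FALSE, vertices = genes)
    g
  }
  list(positive = mk(w > 0, w[w > 0]),
       negative = mk(w < 0, -w[w < 0]))
}

#' Sparsify a differential snapshot to its strongest edges
#'
#' Keeps edges whose absolute differential weight is at or above the
#' `(100 - theta)`-th percentile of the nonzero absolute weights; the kept
#' edges retain their absolute weight as the `weight` attribute. The default
#' `theta = 25` keeps the top quartile.
#'
#' @param dyn a [DynamicSubnetwork-class].
#' @param interval differential snapshot index.
#' @param theta percentage of (nonzero) edges to keep, in (0, 100].
#' @return An [igraph::igraph] over all base genes.
#' @export
thresholdEdges <- function(dyn, interval = 1, theta = 25) {
  if (theta <= 0 || theta > 100) stop("theta must lie in (0, 100]",
                                      call. = FALSE)
  w <- abs(diffWeights(dyn)[, interval])
  genes <- .baseGenes(dyn)
  nz <- w > 0
  keep <- rep(FALSE, length(w))
  if (any(nz)) {
    cut <- quantile(w[nz], probs = (100 - theta) / 100, names = FALSE)
    keep <- nz & w >= cut
  }
  igraph::graph_from_data_frame(
    data.frame(a = dyn@edges[keep, 1], b = dyn@edges[keep, 2],
               weight = w[keep]),
    directed = FALSE, vertices = genes)
}

# union of the per-snapshot thresholded graphs (unweighted)
.thresholdUnionGraph <- function(dyn, theta = 25) {
  genes <- .baseGenes(dyn)
  keep <- rep(FALSE, nrow(dyn@edges))
  for (i in seq_len(ncol(diffWeights(dyn)))) {
    w <- abs(diffWeights(dyn)[, i])
    nz <- w > 0
    if (any(nz)) {
      cut <- quantile(w[nz], probs = (100 - theta) / 100, names = FALSE)
      keep <- keep | (nz & w >= cut)
    }
  }
  igraph::graph_from_data_frame(
    data.frame(a = dyn@edges[keep, 1], b = dyn@edges[keep, 2]),
    directed = FALSE, vertices = genes)
}

#' Per-node graphlet orbit counts (2-4-node graphlets, 15 orbits)
#'
#' Counts, for every node, the induced occurrences of all connected
#' graphlets on 2-4 nodes it touches, split by automorphism orbit (standard
#' orbit numbering 0-14).
#'
#' @param graph a simple undirected [igraph::igraph].
#' @return Node x 15 count matrix with vertex names as rownames.
#' @export
#' @examples
#' tri <- igraph::make_ring(3)
#' graphletOrbitCounts(tri)
graphletOrbitCounts <- function(graph) {
  n <- igraph::vcount(graph)
  ends <- igraph::as_edgelist(graph, names = FALSE)
  counts <- .countOrbitsCpp(n, matrix(as.integer(ends - 1L), ncol = 2))
  rownames(counts) <- igraph::V(graph)$name
  colnames(counts) <- paste0("orbit", 0:14)
  counts
}

# deterministic power iteration for eigenvector centrality on a
# non-negative weight matrix; uniform start, diagonal shift for convergence
.eigenCentrality <- function(w, idx, n, tol = 1e-10, maxit = 10000) {
  if (all(w == 0)) return(numeric(n))
  B <- Matrix::sparseMatrix(i = c(idx[, 1], idx[, 2]),
                            j = c(idx[, 2], idx[, 1]),
                            x = c(w, w), dims = c(n, n))
  shift <- max(Matrix::rowSums(B))
  v <- rep(1 / n, n)
  for (it in seq_len(maxit)) {
    vn <- as.numeric(B %*% v) + shift * v
    vn <- vn / max(vn)
    if (max(abs(vn - v)) < tol) return(vn)
    v <- vn
  }
  v
}

#' The registered nine feature definitions
#'
#' @return Character vector of the nine feature ids accepted by
#'   [computeFeatureMatrix()].
#' @export
featureRegistry <- function() {
  c("wdeg_signed", "wdeg_pos", "wdeg_neg", "clustering", "closeness",
    "eigenvector", "kcore", "orbits", "trend")
}

#' Compute one per-gene dynamic network feature matrix
#'
#' Sequence features concatenate one value per differential snapshot
#' (dimension x - 1): `wdeg_signed` (sum of signed differential weights
#' over incident edges), `wdeg_pos` / `wdeg_neg` (positive / negative
#' channel weighted degree), `clustering` (local clustering coefficient on
#' the thresholded graph), `closeness` (harmonic closeness with edge
#' distance 1/|w| on the thresholded graph; unreachable pairs contribute
#' 0), `eigenvector` (eigenvector centrality on the absolute-weight graph),
#' `kcore` (k-core number on the thresholded graph). `orbits` is the 15-dim
#' graphlet orbit count vector on the union of the thresholded graphs;
#' `trend` is the 3-dim (slope, mean, variance) summary of the signed
#' weighted degree across snapshots.
#'
#' @param dyn a [DynamicSubnetwork-class].
#' @param definitionId one of [featureRegistry()].
#' @param theta sparsification percentage for binary-graph features.
#' @return A [FeatureMatrix-class] over the subnetwork's genes.
#' @export
computeFeatureMatrix <- function(dyn, definitionId, theta = 25) {
  if (!definitionId %in% featureRegistry()) {
    stop("unknown feature definition '", definitionId, "'; registry: ",
         paste(featureRegistry(), collapse = ", "), call. = FALSE)
  }
  genes <- .baseGenes(dyn)
  n <- length(genes)
  idx <- .edgeIndex(dyn, genes)
  W <- diffWeights(dyn)
  nInt <- ncol(W)

  perSnap <- function(fun) {
    m <- vapply(seq_len(nInt), fun, numeric(n))
    matrix(m, nrow = n, dimnames = list(genes, diffIntervals(dyn)))
  }

  vals <- switch(definitionId,
    wdeg_signed = perSnap(function(i) .weightedDegree(W[, i], idx, n)),
    wdeg_pos = perSnap(function(i) .weightedDegree(pmax(W[, i], 0), idx, n)),
    wdeg_neg = perSnap(function(i) .weightedDegree(pmax(-W[, i], 0), idx, n)),
    clustering = perSnap(function(i) {
      g <- thresholdEdges(dyn, i, theta)
      igraph::transitivity(g, type = "local", isolates = "zero")
    }),
    closeness = perSnap(function(i) {
      g <- thresholdEdges(dyn, i, theta)
      if (igraph::ecount(g) == 0) return(numeric(n))
      igraph::harmonic_centrality(
        g, weights = 1 / igraph::E(g)$weight, normalized = FALSE)
    }),
    eigenvector = perSnap(function(i) {
      .eigenCentrality(abs(W[, i]), idx, n)
    }),
    kcore = perSnap(function(i) {
      igraph::coreness(thresholdEdges(dyn, i, theta))
    }),
    orbits = graphletOrbitCounts(.thresholdUnionGraph(dyn, theta)),
    trend = {
      sdeg <- vapply(seq_len(nInt), function(i) {
        .weightedDegree(W[, i], idx, n)
      }, numeric(n))
      sdeg <- matrix(sdeg, nrow = n)
      t0 <- seq_len(nInt) - mean(seq_len(nInt))
      slope <- if (nInt > 1) {
        as.numeric(sdeg %*% t0) / sum(t0^2)
      } else {
        numeric(n)
      }
      vr <- if (nInt > 1) apply(sdeg, 1, var) else numeric(n)
      cbind(slope = slope, mean = rowMeans(sdeg), variance = vr)
    })
  rownames(vals) <- genes
  FeatureMatrix(vals, definitionId,
                provenance = list(theta = theta, scheme = dyn@scheme,
                                  nSnapshots = nInt + 1L))
}

#' Compute all nine feature matrices
#'
#' @inheritParams computeFeatureMatrix
#' @return Named list of nine [FeatureMatrix-class] objects.
#' @export
computeAllFeatures <- function(dyn, theta = 25) {
  ids <- featureRegistry()
  setNames(lapply(ids, computeFeatureMatrix, dyn = dyn, theta = theta), ids)
}
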