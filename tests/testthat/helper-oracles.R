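# Independent oracles and small fixture builders used across the suite.

# dense linear-system solution of the biased random walk with restart:
# pi = r * (I - (1 - r) P')^{-1} q, built straight from the definition
rwrDenseOracle <- function(net, scores, r) {
  nodes <- igraph::V(net)$name
  g <- as.numeric(scores[nodes])
  g[g == 0] <- 1e-3 * min(g[g > 0])
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  W <- sweep(A, 2, g, `*`)
  P <- W / rowSums(W)
  q <- g / sum(g)
  pi <- solve(diag(length(g)) - (1 - r) * t(P), r * q)
  names(pi) <- nodes
  pi / sum(pi)
}

# random connected graph via a random spanning tree plus extra edges
randomConnectedGraph <- function(n, extra = n) {
  to <- vapply(2:n, function(v) sample(v - 1, 1), 0L)
  edges <- cbind(2:n, to)
  more <- matrix(sample(n, 2 * extra, replace = TRUE), ncol = 2)
  more <- more[more[, 1] != more[, 2], , drop = FALSE]
  ids <- sprintf("n%03d", 1:n)
  g <- igraph::graph_from_data_frame(
    data.frame(a = ids[c(edges[, 1], more[, 1])],
               b = ids[c(edges[, 2], more[, 2])]),
    directed = FALSE, vertices = ids)
  igraph::simplify(g)
}

# brute-force graphlet orbit counts: enumerate every 3- and 4-node subset,
# keep connected induced subgraphs, classify by within-subgraph degree
orbitBruteForce <- function(graph) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  counts <- matrix(0, n, 15)
  rownames(counts) <- igraph::V(graph)$name
  counts[, 1] <- rowSums(A)
  classify <- function(sub) {
    S <- A[sub, sub, drop = FALSE]
    deg <- rowSums(S)
    nE <- sum(S) / 2
    k <- length(sub)
    g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected")
    if (!igraph::is_connected(g)) return(NULL)
    maxDeg <- max(deg)
    orb <- if (k == 3) {
      if (nE == 3) rep(3, 3) else ifelse(deg == 1, 1, 2)
    } else if (nE == 3) {
      if (maxDeg == 3) ifelse(deg == 1, 6, 7) else ifelse(deg == 1, 4, 5)
    } else if (nE == 4) {
      if (maxDeg == 3) c(9, 10, 11)[deg] else rep(8, 4)
    } else if (nE == 5) {
      ifelse(deg == 2, 12, 13)
    } else {
      rep(14, 4)
    }
    cbind(sub, orb)
  }
  for (k in 3:4) {
    if (n < k) next
    subs <- combn(n, k)
    for (j in seq_len(ncol(subs))) {
      cl <- classify(subs[, j])
      if (!is.null(cl)) {
        for (i in seq_len(nrow(cl))) {
          counts[cl[i, 1], cl[i, 2] + 1] <- counts[cl[i, 1], cl[i, 2] + 1] + 1
        }
      }
    }
  }
  colnames(counts) <- paste0("orbit", 0:14)
  counts
}

# direct transcription of the Benjamini-Hochberg step-up definition
bhStepUpOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# exhaustive hypergeometric upper tail: enumerate every size-B subset of
# the universe and count those overlapping the first A elements >= ov times
hypergeomEnumOracle <- function(A, B, ov, U) {
  subsets <- combn(U, B)
  hits <- colSums(subsets <= A)
  mean(hits >= ov)
}

# build a DynamicSubnetwork directly from an edge table and a signed
# weight matrix (bypassing propagation) for feature-level tests
makeDyn <- function(edges, w, scheme = "per_snapshot_sum") {
  w <- as.matrix(w)
  intervals <- paste0("t", seq_len(ncol(w)), "->t", seq_len(ncol(w)) + 1)
  colnames(w) <- intervals
  new("DynamicSubnetwork", edges = as.matrix(edges), diffWeights = w,
      intervals = intervals, scheme = scheme)
}

# small deterministic expression study
toyStudy <- function() {
  v <- matrix(c(2, 4, 6,
                1, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  ExpressionStudy(v, age = c(20, 20, 30))
}

# run one synthetic study through propagation, features and CV, returning
# everything the acceptance experiments need
runSyntheticCombo <- function(cfg, truth = NULL, folds = NULL,
                              cohort = "", net = NULL, planting = NULL) {
  if (is.null(net)) net <- generateNetwork(cfg)
  if (is.null(planting)) planting <- plantAgingGenes(net, cfg)
  study <- generateExpression(net, planting, cfg, cohort = cohort)
  if (exprMode(study) == "counts") study <- tmmNormalize(study)
  profiles <- alignToNetwork(aggregateByAge(study), net, "zero")
  snaps <- inferSnapshots(net, profiles)
  dyn <- buildDynamicSubnetwork(normalizeSnapshots(snaps))
  if (is.null(truth)) {
    excl <- DynAgeNet:::generateExclusionLists(
      planting, igraph::V(net)$name, cfg)
    truth <- buildLabels(igraph::V(net)$name,
                         setdiff(planting$planted, planting$hidden), excl)
  }
  if (is.null(folds)) {
    folds <- makeFolds(truth, 5, seed = stableSeed(cfg$seed, "folds"))
  }
  outcomes <- lapply(computeAllFeatures(dyn), trainPredictCv,
                     truth = truth, folds = folds)
  best <- selectBestModel(outcomes)
  list(net = net, planting = planting, dyn = dyn, truth = truth,
       folds = folds, outcomes = outcomes, bestModel = best,
       best = outcomes[[best]])
}
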