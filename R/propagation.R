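## Expression-biased random walk with restart over the interaction network.
## The transition probability into a neighbour is proportional to the
## neighbour's node score, the restart distribution is proportional to the
## scores, and the flux through a directed edge is the stationary
## probability of its source times the transition probability. Taking the
## smaller of the two directed fluxes per interaction yields the weighted
## age-specific snapshot.

#' Propagation configuration
#'
#' @param restart restart probability r in (0, 1).
#' @param tolerance L1 convergence tolerance of the power iteration.
#' @param maxIterations iteration cap; exceeding it is an error.
#' @param zeroFloorFactor zero node scores are replaced by this factor times
#'   the smallest positive score, keeping the chain irreducible.
#' @return A `PropagationConfig` list.
#' @export
propagationConfig <- function(restart = 0.5, tolerance = 1e-10,
                              maxIterations = 10000,
                              zeroFloorFactor = 1e-3) {
  if (restart <= 0 || restart >= 1) stop("restart must lie in (0, 1)",
                                         call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  structure(list(restart = restart, tolerance = tolerance,
                 maxIterations = assertCount(maxIterations, "maxIterations"),
                 zeroFloorFactor = zeroFloorFactor),
            class = "PropagationConfig")
}

#' Expression-biased random walk with restart and directed edge fluxes
#'
#' Solves `pi = (1 - r) P' pi + r q` by power iteration started from the
#' restart distribution q, where `P[i, j] = g_j / sum(g over neighbours of
#' i)` and `q = g / sum(g)`. The flux of directed edge (i, j) is
#' `pi_i * P[i, j]`; all quantities are invariant to rescaling the scores.
#'
#' @param net connected undirected [igraph::igraph].
#' @param scores named non-negative node scores covering every vertex, at
#'   least one positive; zeros are floored per the config.
#' @param cfg a [propagationConfig()].
#' @return A `PropagationResult` list with `pi` (stationary distribution),
#'   `P` (sparse transition matrix), `q` (restart distribution), `flux`
#'   (sparse directed edge-flux matrix), `iterations` and `residual`.
#' @export
netwalkEdgeFlux <- function(net, scores, cfg = propagationConfig()) {
  if (!igraph::is_connected(net)) {
    stop("propagation requires a connected network", call. = FALSE)
  }
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(scores))) {
    stop("scores must cover every network node", call. = FALSE)
  }
  g <- as.numeric(scores[nodes])
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("scores must be finite and non-negative", call. = FALSE)
  }
  if (!any(g > 0)) stop("at least one positive score required",
                        call. = FALSE)
  floorVal <- cfg$zeroFloorFactor * min(g[g > 0])
  g[g == 0] <- floorVal

  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  # W[i, j] = g_j for each edge (i, j); row-normalize to P
  W <- A %*% Matrix::Diagonal(x = g)
  rs <- Matrix::rowSums(W)
  P <- Matrix::Diagonal(x = 1 / rs) %*% W
  q <- g / sum(g)
  r <- cfg$restart
  Pt <- Matrix::t(P)

  pi <- q
  iter <- 0L
  repeat {
    piNew <- as.numeric((1 - r) * (Pt %*% pi)) + r * q
    resid <- sum(abs(piNew - pi))
    pi <- piNew
    iter <- iter + 1L
    if (resid < cfg$tolerance) break
    if (iter >= cfg$maxIterations) {
      stop(sprintf("power iteration did not converge in %d iterations (L1 residual %.3e)",
                   iter, resid), call. = FALSE)
    }
  }
  pi <- pi / sum(pi)
  flux <- Matrix::Diagonal(x = pi) %*% P
  dimnames(P) <- dimnames(flux) <- list(nodes, nodes)
  names(pi) <- names(q) <- nodes
  structure(list(pi = pi, P = P, q = q, flux = flux,
                 iterations = iter, residual = resid,
                 restart = r),
            class = "PropagationResult")
}

#' Weighted snapshot from directed edge fluxes
#'
#' Per undirected interaction, the smaller of the two directed fluxes
#' becomes the snapshot edge weight.
#'
#' @param res a `PropagationResult` from [netwalkEdgeFlux()].
#' @param net the network the result was computed on.
#' @param age age label for the snapshot column.
#' @return A one-column [SnapshotSeries-class].
#' @export
snapshotFromFlux <- function(res, net, age = "snapshot") {
  ends <- igraph::as_edgelist(net)
  # order edges deterministically by gene pair
  a <- pmin(ends[, 1], ends[, 2])
  b <- pmax(ends[, 1], ends[, 2])
  o <- order(a, b)
  a <- a[o]; b <- b[o]
  w <- pmin(res$flux[cbind(a, b)], res$flux[cbind(b, a)])
  SnapshotSeries(cbind(a, b), matrix(w, ncol = 1), age)
}

#' Infer one weighted snapshot per age
#'
#' Runs the biased random walk once per age column of the profiles and
#' collects the per-age snapshots in ascending age order.
#'
#' @param net connected network whose nodes equal the profile genes.
#' @param profiles an [AgeProfiles-class].
#' @param cfg a [propagationConfig()].
#' @return A [SnapshotSeries-class] with one column per age.
#' @export
inferSnapshots <- function(net, profiles, cfg = propagationConfig()) {
  nodes <- sort(igraph::V(net)$name)
  if (!identical(sort(profileGenes(profiles)), nodes)) {
    stop("profile genes must equal the network node set", call. = FALSE)
  }
  s <- profileScores(profiles)
  ages <- profileAges(profiles)
  snaps <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    res <- tryCatch(
      netwalkEdgeFlux(net, s[, i], cfg),
      error = function(e) {
        stop("propagation failed at age ", ages[i], ": ",
             conditionMessage(e), call. = FALSE)
      })
    snaps[[i]] <- snapshotFromFlux(res, net, ages[i])
  }
  SnapshotSeries(snapshotEdges(snaps[[1]]),
                 do.call(cbind, lapply(snaps, snapshotWeights)),
                 ages)
}
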