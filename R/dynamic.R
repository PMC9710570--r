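## From per-age snapshots to the weighted dynamic aging-specific
## subnetwork: normalize weights across the x snapshots, then build x - 1
## differential snapshots whose edge weights are the relative weight change
## between consecutive ages, scaled to [-100, 100].

#' Normalize snapshot weights across ages
#'
#' `per_snapshot_sum` (default) divides each snapshot's weights by that
#' snapshot's total, removing the per-age nuisance scale; `pooled_minmax`
#' affinely maps all weights to `[0, 1]` using the global min/max over all
#' snapshots (degenerate all-equal input maps to 0 with a warning).
#'
#' @param snaps a [SnapshotSeries-class] with >= 2 snapshots.
#' @param scheme `"per_snapshot_sum"` or `"pooled_minmax"`.
#' @return A [SnapshotSeries-class] with the scheme recorded.
#' @export
normalizeSnapshots <- function(snaps,
                               scheme = c("per_snapshot_sum",
                                          "pooled_minmax")) {
  scheme <- match.arg(scheme)
  w <- snapshotWeights(snaps)
  if (ncol(w) < 2) stop("need >= 2 snapshots to normalize", call. = FALSE)
  if (scheme == "per_snapshot_sum") {
    tot <- colSums(w)
    if (any(tot == 0)) {
      stop("snapshot with all-zero weights at age ",
           snapshotAges(snaps)[which(tot == 0)[1]], call. = FALSE)
    }
    w <- sweep(w, 2, tot, `/`)
  } else {
    lo <- min(w); hi <- max(w)
    if (hi == lo) {
      warning("degenerate weight range; all normalized weights set to 0")
      w[] <- 0
    } else {
      w <- (w - lo) / (hi - lo)
    }
  }
  SnapshotSeries(snapshotEdges(snaps), w, snapshotAges(snaps),
                 scheme = scheme)
}

#' Differential edge weight between consecutive snapshots
#'
#' Relative weight change `(w_next - w_i) * 100 / (w_next + w_i)`, with the
#' convention that a 0/0 pair (edge silent at both ages) gives 0. Values lie
#' in `[-100, 100]`; vectorized over its arguments.
#'
#' @param w current snapshot weight(s), non-negative.
#' @param wNext next snapshot weight(s), non-negative.
#' @return Differential weight(s) in `[-100, 100]`.
#' @export
#' @examples
#' differentialWeight(1, 3)   # 50
#' differentialWeight(5, 0)   # -100
#' differentialWeight(0, 0)   # 0
differentialWeight <- function(w, wNext) {
  if (any(w < 0) || any(wNext < 0)) {
    stop("snapshot weights must be non-negative", call. = FALSE)
  }
  denom <- w + wNext
  out <- ifelse(denom == 0, 0, (wNext - w) * 100 / denom)
  out
}

#' Build the weighted dynamic subnetwork of differential snapshots
#'
#' Applies [differentialWeight()] edge-wise to every pair of consecutive
#' normalized snapshots, producing x - 1 differential snapshots in age
#' order.
#'
#' @param snaps a normalized [SnapshotSeries-class] (>= 2 snapshots; see
#'   [normalizeSnapshots()]).
#' @return A [DynamicSubnetwork-class].
#' @export
buildDynamicSubnetwork <- function(snaps) {
  w <- snapshotWeights(snaps)
  if (ncol(w) < 2) stop("need >= 2 snapshots", call. = FALSE)
  if (!nzchar(normScheme(snaps))) {
    stop("snapshots must be normalized first (see normalizeSnapshots)",
         call. = FALSE)
  }
  x <- ncol(w)
  d <- vapply(seq_len(x - 1), function(i) {
    differentialWeight(w[, i], w[, i + 1])
  }, numeric(nrow(w)))
  d <- matrix(d, nrow = nrow(w))
  ages <- snapshotAges(snaps)
  intervals <- paste(ages[-x], ages[-1], sep = "->")
  colnames(d) <- intervals
  nZeroZero <- sum(d == 0 & w[, -x, drop = FALSE] == 0 &
                   w[, -1, drop = FALSE] == 0)
  if (nZeroZero > 0) {
    message("buildDynamicSubnetwork: ", nZeroZero,
            " zero/zero edge pair(s) assigned differential weight 0")
  }
  new("DynamicSubnetwork", edges = snapshotEdges(snaps), diffWeights = d,
      intervals = intervals, scheme = normScheme(snaps))
}
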