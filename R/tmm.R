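## Trimmed mean of M-values (TMM) between-sample normalization for count
## data, following the Robinson-Oshlack algorithm: per sample, log2 relative
## abundance ratios (M) and mean log2 abundances (A) against a reference
## sample are double-trimmed, and the scale factor is two to the
## precision-weighted mean of the retained M values.

#' TMM configuration
#'
#' Canonical defaults: trim 30% of the most extreme M values and 5% of the
#' most extreme A values on each side; reference sample = the one whose
#' upper-quartile relative abundance is closest to the mean upper quartile.
#'
#' @param trimM two-sided trim fraction on log-ratios M, in `[0, 0.5)`.
#' @param trimA two-sided trim fraction on mean abundances A, in `[0, 0.5)`.
#' @return A `TmmConfig` list.
#' @export
tmmConfig <- function(trimM = 0.30, trimA = 0.05) {
  if (trimM < 0 || trimM >= 0.5 || trimA < 0 || trimA >= 0.5) {
    stop("trim fractions must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(trimM = trimM, trimA = trimA), class = "TmmConfig")
}

# one sample vs reference; obs/ref are count vectors, nO/nR library sizes
.tmmFactorPair <- function(obs, ref, nO, nR, cfg) {
  keep <- obs > 0 & ref > 0              # genes zero in either are excluded
  obs <- obs[keep]
  ref <- ref[keep]
  logR <- log2((obs / nO) / (ref / nR))            # M
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2    # A
  v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref) # ~binomial var
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * cfg$trimM) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * cfg$trimA) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
          rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
       sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Per-sample TMM scale factors
#'
#' @param counts non-negative gene x sample count matrix (>= 2 samples).
#' @param cfg a [tmmConfig()].
#' @return Named per-sample factors whose geometric mean is 1; multiply a
#'   sample's library size by its factor to obtain its effective library
#'   size.
#' @export
#' @examples
#' set.seed(7)
#' counts <- matrix(rnbinom(60, mu = 50, size = 5), 20, 3,
#'                  dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
#' tmmFactors(counts)
tmmFactors <- function(counts, cfg = tmmConfig()) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs >= 2 samples", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample with all-zero counts: ",
         colnames(counts)[which(lib == 0)[1]], call. = FALSE)
  }
  # reference: upper-quartile relative abundance closest to the mean
  f75 <- vapply(seq_len(ncol(counts)), function(j) {
    quantile(counts[, j] / lib[j], 0.75, names = FALSE)
  }, 0)
  refIdx <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == refIdx) return(1)
    .tmmFactorPair(counts[, j], counts[, refIdx], lib[j], lib[refIdx], cfg)
  }, 0)
  f <- f / exp(mean(log(f)))             # geometric mean 1
  names(f) <- colnames(counts)
  f
}

#' Apply TMM factors to a count matrix
#'
#' Scales each sample by its effective library size (library size x TMM
#' factor), rescaled so that the geometric-mean effective library is
#' preserved; output is on the original count scale.
#'
#' @param counts gene x sample count matrix.
#' @param factors factors from [tmmFactors()].
#' @return Normalized matrix of the same shape.
#' @export
applyTmm <- function(counts, factors = tmmFactors(counts)) {
  counts <- as.matrix(counts)
  eff <- colSums(counts) * factors
  scale <- exp(mean(log(eff))) / eff
  sweep(counts, 2, scale, `*`)
}

#' TMM-normalize a counts-mode expression study
#'
#' @param study counts-mode [ExpressionStudy-class].
#' @param cfg a [tmmConfig()].
#' @return The study with normalized values (mode left as `"counts"`).
#' @export
tmmNormalize <- function(study, cfg = tmmConfig()) {
  if (exprMode(study) != "counts") {
    stop("tmmNormalize expects a counts-mode study", call. = FALSE)
  }
  v <- applyTmm(exprValues(study), tmmFactors(exprValues(study), cfg))
  a <- sampleAges(study)
  if (is.numeric(a)) {
    ExpressionStudy(v, age = a, mode = "counts")
  } else {
    ExpressionStudy(v, ageGroup = a, mode = "counts")
  }
}
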