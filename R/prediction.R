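## Cross-validated supervised prediction of aging-related genes: stratified
## folds shared across models and subnetworks, per-fold standardization,
## L2-regularized logistic regression (class-weighted for the ~6% positive
## rate), precision-recall accuracy metrics and permutation significance.

#' Classifier configuration
#'
#' @param regStrength inverse regularization strength C > 0; the ridge
#'   penalty applied by the fit is `lambda = 1 / (C * n_train)`.
#' @param classWeight `"balanced"` (each class contributes equal total
#'   weight) or `"none"`.
#' @param threshold probability threshold for calling a gene
#'   aging-related, in (0, 1).
#' @param maxIterations optimizer iteration cap.
#' @return A `ClassifierConfig` list.
#' @export
classifierConfig <- function(regStrength = 1.0,
                             classWeight = c("balanced", "none"),
                             threshold = 0.5, maxIterations = 1e5) {
  classWeight <- match.arg(classWeight)
  if (regStrength <= 0) stop("regStrength must be > 0", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(regStrength = regStrength, classWeight = classWeight,
                 threshold = threshold, maxIterations = maxIterations),
            class = "ClassifierConfig")
}

#' Stratified cross-validation folds
#'
#' Deterministic given (labels, k, seed): positives and negatives are each
#' shuffled under the seed and dealt round-robin, so per-fold positive
#' counts differ by at most one. The same seed therefore yields identical
#' folds for every model and every subnetwork sharing the label set.
#'
#' @param truth a [GroundTruth-class].
#' @param k number of folds.
#' @param seed integer seed.
#' @return A [FoldAssignment-class].
#' @export
makeFolds <- function(truth, k = 5, seed = 1) {
  k <- assertCount(k, "k", 2)
  pos <- positives(truth)
  neg <- negatives(truth)
  if (length(pos) < 2 || length(neg) < 2 || length(pos) + length(neg) < k) {
    stop("too few labeled genes: need at least 2 of each class and k in ",
         "total (", length(pos), " positives, ", length(neg),
         " negatives for k = ", k, ")", call. = FALSE)
  }
  withSeed(seed, {
    # deal shuffled positives round-robin, then continue with the
    # negatives from the next fold so total fold sizes differ by <= 1
    folds <- c(
      setNames((seq_along(pos) - 1L) %% k, sample(pos)),
      setNames((length(pos) + seq_along(neg) - 1L) %% k, sample(neg)))
  })
  folds <- folds[order(names(folds))]
  storage.mode(folds) <- "integer"
  new("FoldAssignment", folds = folds, k = k, seed = as.integer(seed))
}

# weighted ridge logistic regression via glmnet; deterministic
.fitLogistic <- function(x, y, cfg) {
  n <- nrow(x)
  wts <- rep(1, n)
  if (cfg$classWeight == "balanced") {
    wts <- n / (2 * ifelse(y == 1, sum(y == 1), sum(y == 0)))
  }
  lambda <- 1 / (cfg$regStrength * n)
  if (ncol(x) < 2) x <- cbind(x, .pad = 0)  # glmnet needs >= 2 columns
  # warm-started path down to the target penalty: far more reliable than a
  # cold fit at one small lambda
  path <- lambda * 10^seq(3, 0, length.out = 25)
  fit <- withCallingHandlers(
    glmnet::glmnet(x, factor(y, levels = c(0, 1)),
                   family = "binomial", alpha = 0, lambda = path,
                   weights = wts, standardize = FALSE,
                   maxit = cfg$maxIterations),
    warning = function(w) {
      # glmnet warns about small minority classes; expected at ~6%
      # positives and harmless for the ridge fit
      if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(fit = fit, lambda = lambda)
}

.predictLogistic <- function(fit, x) {
  if (ncol(x) < 2) x <- cbind(x, .pad = 0)
  as.numeric(predict(fit$fit, newx = x, s = fit$lambda,
                     type = "response"))
}

#' Area under the precision-recall curve (average precision)
#'
#' Descending-score sweep with tied scores processed as a single threshold;
#' `sum(precision * delta recall)` over the positive-containing thresholds.
#' Constant scores give the positive fraction (the chance level).
#'
#' @param scores numeric scores, higher = more aging-like.
#' @param labels logical or 0/1 ground-truth labels.
#' @return AUPR in `[0, 1]`.
#' @export
aucPR <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  nPos <- sum(labels)
  if (nPos == 0 || nPos == length(labels)) {
    stop("AUPR needs at least one positive and one negative", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp <- cumsum(!duplicated(s))          # tie groups in descending order
  tp <- cumsum(y)
  nSeen <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)  # last index of each tie group
  tpG <- tp[last]
  nG <- nSeen[last]
  dTp <- diff(c(0, tpG))
  prec <- tpG / nG
  sum(prec * dTp) / nPos
}

#' Precision, recall and F-score of a predicted gene set
#'
#' Precision is defined as 0 (with a `no_predictions` flag) when nothing is
#' predicted; F is 0 when precision and recall are both 0.
#'
#' @param predicted character vector of predicted aging-related genes.
#' @param truth a [GroundTruth-class] (or list with `positives` and
#'   `negatives`).
#' @param universe genes over which the prediction was made; defaults to
#'   the labeled genes.
#' @return Named vector `(precision, recall, fscore)` with attribute
#'   `no_predictions`.
#' @export
precisionRecallFscore <- function(predicted, truth,
                                  universe = labeledGenes(truth)) {
  pos <- intersect(positives(truth), universe)
  tp <- length(intersect(predicted, pos))
  fp <- length(setdiff(predicted, pos))
  fn <- length(setdiff(pos, predicted))
  none <- (tp + fp) == 0
  precision <- if (none) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(c(precision = precision, recall = recall, fscore = f),
            no_predictions = none)
}

#' Train and evaluate one predictive model by cross-validation
#'
#' Per fold: each feature coordinate is standardized by the training-fold
#' mean and standard deviation (coordinates with zero training sd are
#' dropped for that fold), a weighted ridge logistic regression is fitted
#' on the training genes and the held-out genes are scored. Every labeled
#' gene is scored exactly once, in its test fold.
#'
#' @param features a [FeatureMatrix-class] covering all labeled genes.
#' @param truth a [GroundTruth-class].
#' @param folds a [FoldAssignment-class] over the labeled genes.
#' @param cfg a [classifierConfig()].
#' @return A [PredictionOutcome-class].
#' @export
trainPredictCv <- function(features, truth, folds,
                           cfg = classifierConfig()) {
  fm <- featureValues(features)
  ids <- names(foldIds(folds))
  if (!all(ids %in% rownames(fm))) {
    stop("features must cover all labeled genes", call. = FALSE)
  }
  X <- fm[ids, , drop = FALSE]
  y <- as.integer(ids %in% positives(truth))
  fid <- foldIds(folds)[ids]
  k <- nFolds(folds)

  scores <- setNames(rep(NA_real_, length(ids)), ids)
  perFold <- vector("list", k)
  for (f in 0:(k - 1)) {
    tr <- fid != f
    te <- !tr
    if (length(unique(y[tr])) < 2) {
      stop("training data of fold ", f, " contains a single class",
           call. = FALSE)
    }
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, sd)
    keep <- sg > 0
    if (!any(keep)) {
      # completely constant features: chance-level scores
      scores[te] <- mean(y[tr])
    } else {
      Xtr <- sweep(sweep(X[tr, keep, drop = FALSE], 2, mu[keep]), 2,
                   sg[keep], `/`)
      Xte <- sweep(sweep(X[te, keep, drop = FALSE], 2, mu[keep]), 2,
                   sg[keep], `/`)
      fit <- .fitLogistic(Xtr, y[tr], cfg)
      scores[te] <- .predictLogistic(fit, Xte)
    }
    predF <- ids[te][scores[te] >= cfg$threshold]
    prf <- precisionRecallFscore(predF, truth, universe = ids[te])
    # a test fold may lack one class (e.g. under label permutation); its
    # AUPR is undefined and excluded from the fold average
    auprF <- if (length(unique(y[te])) < 2) {
      NA_real_
    } else {
      aucPR(scores[te], y[te] == 1)
    }
    perFold[[f + 1]] <- data.frame(
      fold = f, aupr = auprF,
      precision = prf["precision"], recall = prf["recall"],
      fscore = prf["fscore"], row.names = NULL)
  }
  perFold <- do.call(rbind, perFold)
  if (all(is.na(perFold$aupr))) {
    stop("no test fold contains both classes", call. = FALSE)
  }
  summary <- c(aupr = mean(perFold$aupr, na.rm = TRUE),
               precision = mean(perFold$precision),
               recall = mean(perFold$recall),
               fscore = mean(perFold$fscore))
  new("PredictionOutcome", modelId = featureId(features),
      scores = scores, labels = scores >= cfg$threshold, folds = fid,
      perFold = perFold, summary = summary, threshold = cfg$threshold,
      flags = list())
}

#' Permutation significance of cross-validated metrics
#'
#' Permutes the labels within the labeled gene set B times, re-runs the
#' identical fold/standardize/fit/score pipeline per permutation, and
#' reports the empirical upper-tail p-value
#' `(1 + #{null >= observed}) / (B + 1)` for each fold-averaged metric.
#'
#' @param features,truth,folds,cfg as in [trainPredictCv()].
#' @param B number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @param observed optionally, a precomputed [PredictionOutcome-class] for
#'   the unpermuted labels.
#' @return List with `p` (named p-values), `observed` (metrics) and `null`
#'   (B x 4 matrix of null metrics).
#' @export
permutationSignificance <- function(features, truth, folds,
                                    cfg = classifierConfig(), B = 199,
                                    seed = 1, observed = NULL) {
  B <- assertCount(B, "B", 99)
  if (is.null(observed)) {
    observed <- trainPredictCv(features, truth, folds, cfg)
  }
  obs <- cvMetrics(observed)
  ids <- names(foldIds(folds))
  nPos <- length(intersect(ids, positives(truth)))
  null <- matrix(NA_real_, B, 4,
                 dimnames = list(NULL, names(obs)))
  perms <- withSeed(seed, {
    lapply(seq_len(B), function(b) sample(ids, nPos))
  })
  for (b in seq_len(B)) {
    permTruth <- GroundTruth(perms[[b]], setdiff(ids, perms[[b]]))
    out <- trainPredictCv(features, permTruth, folds, cfg)
    null[b, ] <- cvMetrics(out)[colnames(null)]
  }
  p <- vapply(names(obs), function(m) {
    (1 + sum(null[, m] >= obs[m])) / (B + 1)
  }, 0)
  list(p = p, observed = obs, null = null)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, monotone and capped at 1.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Select the best predictive model by fold-averaged AUPR
#'
#' Ties are broken by higher F-score, then by lexicographic model id.
#'
#' @param outcomes list of [PredictionOutcome-class] objects.
#' @return The winning model id (character).
#' @export
selectBestModel <- function(outcomes) {
  stopifnot(length(outcomes) >= 1)
  tab <- data.frame(
    id = vapply(outcomes, modelId, ""),
    aupr = vapply(outcomes, function(o) cvMetrics(o)["aupr"], 0),
    fscore = vapply(outcomes, function(o) cvMetrics(o)["fscore"], 0))
  tab <- tab[order(-tab$aupr, -tab$fscore, tab$id), ]
  tab$id[1]
}
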