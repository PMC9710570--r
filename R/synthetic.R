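## Synthetic study generator: a scale-free interaction network with a
## planted, topologically clustered set of aging genes whose expression
## trajectories drift monotonically with age. Provides known ground truth
## (including a hidden fraction of positives, mimicking incomplete curation)
## for every downstream pipeline stage.

#' Configuration of a synthetic aging study
#'
#' Defaults are the package's reference study conditions: a 500-gene
#' scale-free network (preferential attachment, m = 3), six age points
#' (decade midpoints 25..75 years), 10 samples per age, 6% planted
#' aging-related genes with signal strength 1 (expression changes by up to
#' +/-100% across the age range), 30% of planted genes withheld from the
#' visible positive labels, and multiplicative log-normal noise with sdlog
#' 0.3. Counts mode adds RNA-seq-like sequencing depth and negative-binomial
#' dispersion to exercise TMM normalization.
#'
#' @param nGenes number of genes (network nodes).
#' @param m preferential-attachment growth parameter (edges per new node).
#' @param nAges number of distinct age points x (>= 2).
#' @param samplesPerAge samples drawn at each age.
#' @param agingFraction fraction of genes planted as aging-related,
#'   in (0, 0.5).
#' @param signalStrength s >= 0; planted mean at age index t is
#'   `b * (1 + s * beta * t/(x-1))`, floored at 0.
#' @param hiddenFraction share of planted genes withheld from the visible
#'   positive label list, in `[0, 1)`.
#' @param noiseSd sdlog of the multiplicative log-normal sample noise.
#' @param mode `"intensity"` (default) or `"counts"`.
#' @param depth expected per-sample sequencing depth (counts mode).
#' @param depthSdLog sdlog of the per-sample log-normal depth variation.
#' @param dispersion negative-binomial dispersion phi (counts mode;
#'   `size = 1/phi`).
#' @param clusterSize target size of each planted topological cluster.
#' @param uniformPlacement place planted genes uniformly at random instead
#'   of in network clusters (null-experiment option).
#' @param exclusionFraction size of each of the five exclusion lists as a
#'   fraction of `nGenes`.
#' @param contamination fraction of non-planted genes mixed into the planted
#'   pathway gene set (count = `ceiling(contamination * n_planted)`).
#' @param seed master seed; every generator stage derives its own stream
#'   from it via [stableSeed()].
#' @return A `StudyConfig` (validated list).
#' @export
studyConfig <- function(nGenes = 500, m = 3, nAges = 6, samplesPerAge = 10,
                        agingFraction = 0.06, signalStrength = 1.0,
                        hiddenFraction = 0.3, noiseSd = 0.3,
                        mode = c("intensity", "counts"), depth = 1e6,
                        depthSdLog = 0.2, dispersion = 0.1,
                        clusterSize = 10, uniformPlacement = FALSE,
                        exclusionFraction = 0.03, contamination = 0.2,
                        seed = 1) {
  mode <- match.arg(mode)
  cfg <- list(nGenes = assertCount(nGenes, "nGenes", 3),
              m = assertCount(m, "m", 1),
              nAges = assertCount(nAges, "nAges", 2),
              samplesPerAge = assertCount(samplesPerAge, "samplesPerAge", 1),
              agingFraction = agingFraction,
              signalStrength = signalStrength,
              hiddenFraction = hiddenFraction,
              noiseSd = noiseSd, mode = mode, depth = depth,
              depthSdLog = depthSdLog, dispersion = dispersion,
              clusterSize = assertCount(clusterSize, "clusterSize", 1),
              uniformPlacement = isTRUE(uniformPlacement),
              exclusionFraction = exclusionFraction,
              contamination = contamination,
              seed = assertCount(seed, "seed", 0))
  if (!(cfg$agingFraction > 0 && cfg$agingFraction < 0.5)) {
    stop("agingFraction must lie in (0, 0.5)", call. = FALSE)
  }
  if (cfg$hiddenFraction < 0 || cfg$hiddenFraction >= 1) {
    stop("hiddenFraction must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$signalStrength < 0) stop("signalStrength must be >= 0",
                                   call. = FALSE)
  if (cfg$noiseSd <= 0) stop("noiseSd must be > 0", call. = FALSE)
  if (cfg$nGenes <= cfg$m) stop("nGenes must exceed m", call. = FALSE)
  structure(cfg, class = "StudyConfig")
}

.geneIds <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a connected scale-free network
#'
#' Preferential attachment: m initial nodes, each subsequent node attaches
#' to m distinct existing nodes with probability proportional to degree (the
#' first added node connects to all initial nodes, which guarantees
#' connectivity). Edge count is exactly `m * (nGenes - m)`.
#'
#' @param cfg a [studyConfig()].
#' @return An undirected simple [igraph::igraph] on `nGenes` named nodes.
#' @export
generateNetwork <- function(cfg) {
  n <- cfg$nGenes
  m <- cfg$m
  withSeed(stableSeed(cfg$seed, "network"), {
    deg <- integer(n)
    from <- integer(m * (n - m))
    to <- integer(m * (n - m))
    k <- 0L
    for (v in (m + 1L):n) {
      targets <- if (v == m + 1L) {
        seq_len(m)
      } else {
        # weighted sampling without replacement by current degree
        sample(v - 1L, m, prob = deg[seq_len(v - 1L)])
      }
      idx <- k + seq_len(m)
      from[idx] <- v
      to[idx] <- targets
      k <- k + m
      deg[v] <- deg[v] + m
      deg[targets] <- deg[targets] + 1L
    }
    ids <- .geneIds(n)
    igraph::graph_from_data_frame(
      data.frame(a = ids[from], b = ids[to]),
      directed = FALSE, vertices = ids)
  })
}

#' Plant a clustered set of aging-related genes
#'
#' Grows `round(agingFraction * nGenes)` planted genes by seeded
#' breadth-first expansion from randomly chosen high-degree seed nodes (top
#' degree decile), so planted genes form topological clusters whose
#' propagation fluxes change coherently with age. A `hiddenFraction` share
#' of planted genes is withheld from the visible positive label list, and
#' each planted gene gets an expression trend direction beta of +1 or -1
#' with equal probability.
#'
#' @param net network from [generateNetwork()].
#' @param cfg a [studyConfig()].
#' @return List with `planted`, `hidden` (subset of planted) and `beta`
#'   (named +/-1 vector over planted genes).
#' @export
plantAgingGenes <- function(net, cfg) {
  n <- igraph::vcount(net)
  nPlant <- round(cfg$agingFraction * n)
  if (nPlant < 1) stop("agingFraction * nGenes < 1", call. = FALSE)
  ids <- igraph::V(net)$name
  deg <- igraph::degree(net)
  withSeed(stableSeed(cfg$seed, "plant"), {
    planted <- character(0)
    if (cfg$uniformPlacement) {
      planted <- sample(ids, nPlant)
    } else {
      hiDeg <- ids[deg >= quantile(deg, 0.9)]
      while (length(planted) < nPlant) {
        pool <- setdiff(hiDeg, planted)
        if (!length(pool)) pool <- setdiff(ids, planted)
        seedGene <- sample(pool, 1)
        want <- min(cfg$clusterSize, nPlant - length(planted))
        # breadth-first growth from the seed, skipping already-planted genes
        ord <- as.integer(igraph::bfs(net, root = seedGene, order = TRUE)$order)
        grown <- setdiff(igraph::V(net)$name[ord], planted)[seq_len(want)]
        planted <- c(planted, grown)
      }
    }
    hidden <- sample(planted, round(cfg$hiddenFraction * length(planted)))
    beta <- sample(c(-1, 1), length(planted), replace = TRUE)
    names(beta) <- planted
    list(planted = planted, hidden = hidden, beta = beta)
  })
}

#' Generate expression with a planted age trend
#'
#' Baselines are log-normal (`meanlog = 5`, `sdlog = 1`). For a planted gene
#' with direction beta, the mean at age index t in 0..x-1 is
#' `b * (1 + s * beta * t/(x-1))` floored at 0; other genes keep their
#' baseline. Intensity mode multiplies each sample by
#' `exp(N(0, noiseSd))` noise; counts mode draws negative-binomial counts
#' with per-sample log-normal depth and composition-preserving gene
#' proportions (so depth and composition bias exercise TMM).
#'
#' @param net network (defines the gene set).
#' @param planting result of [plantAgingGenes()].
#' @param cfg a [studyConfig()].
#' @param cohort label selecting an independent measurement realization of
#'   the same underlying biology (distinct noise / sampling stream), like
#'   separate expression cohorts profiling one organism.
#' @return An [ExpressionStudy-class] with numeric ages.
#' @export
generateExpression <- function(net, planting, cfg, cohort = "") {
  ids <- igraph::V(net)$name
  n <- length(ids)
  x <- cfg$nAges
  ages <- 25 + 10 * (0:(x - 1))          # decade midpoints in years
  withSeed(stableSeed(cfg$seed, "expression", cohort), {
    b <- rlnorm(n, meanlog = 5, sdlog = 1)
    names(b) <- ids
    trend <- matrix(rep(b, x), nrow = n, dimnames = list(ids, NULL))
    tIdx <- (0:(x - 1)) / (x - 1)
    for (g in planting$planted) {
      trend[g, ] <- pmax(0, b[g] *
        (1 + cfg$signalStrength * planting$beta[g] * tIdx))
    }
    nSamp <- x * cfg$samplesPerAge
    sampleAge <- rep(ages, each = cfg$samplesPerAge)
    sampleIds <- sprintf("s_a%02d_r%02d", sampleAge,
                         rep(seq_len(cfg$samplesPerAge), times = x))
    values <- matrix(0, n, nSamp, dimnames = list(ids, sampleIds))
    for (j in seq_len(nSamp)) {
      mu <- trend[, match(sampleAge[j], ages)]
      if (cfg$mode == "intensity") {
        values[, j] <- mu * exp(rnorm(n, 0, cfg$noiseSd))
      } else {
        depthJ <- cfg$depth * rlnorm(1, 0, cfg$depthSdLog)
        p <- mu / sum(mu)
        values[, j] <- rnbinom(n, mu = depthJ * p, size = 1 / cfg$dispersion)
      }
    }
    ExpressionStudy(values, age = sampleAge, mode = cfg$mode)
  })
}

#' Generate gene sets enriched in the planted class
#'
#' One `aging_pathway` set containing all planted genes plus
#' `ceiling(contamination * n_planted)` random non-planted genes, and four
#' random sets of matched size.
#'
#' @param planting result of [plantAgingGenes()].
#' @param genes all gene ids (network nodes).
#' @param cfg a [studyConfig()].
#' @return A [GeneSetCollection-class] of five sets.
#' @export
generateGeneSets <- function(planting, genes, cfg) {
  withSeed(stableSeed(cfg$seed, "genesets"), {
    planted <- planting$planted
    nContam <- ceiling(cfg$contamination * length(planted))
    contam <- sample(setdiff(genes, planted), nContam)
    aging <- c(planted, contam)
    sets <- c(list(aging_pathway = aging),
              lapply(1:4, function(i) sample(genes, length(aging))))
    names(sets)[2:5] <- paste0("random_set_", 1:4)
    GeneSetCollection(sets, c("planted aging module plus contamination",
                              rep("size-matched random set", 4)))
  })
}

#' Generate the five exclusion gene lists
#'
#' Random sets of non-planted genes (so they never contain a visible or
#' hidden positive), mimicking additional curated aging datasets whose
#' members are removed from the negative label pool.
#'
#' @inheritParams generateGeneSets
#' @return List of five character vectors.
#' @keywords internal
generateExclusionLists <- function(planting, genes, cfg) {
  withSeed(stableSeed(cfg$seed, "exclusions"), {
    pool <- setdiff(genes, planting$planted)
    size <- max(1L, round(cfg$exclusionFraction * length(genes)))
    lapply(1:5, function(i) sample(pool, size))
  })
}

#' Generate a complete synthetic study on disk
#'
#' Writes the edge list, expression matrix + sample metadata, visible
#' positive labels (planted minus hidden), five exclusion lists, the GMT
#' gene sets and a JSON manifest recording the configuration and seed. All
#' files re-read into the in-memory objects by the package's readers.
#'
#' @param cfg a [studyConfig()].
#' @param outDir writable output directory (created if missing).
#' @return Invisibly, a list with the in-memory objects (`network`, `study`,
#'   `planting`, `geneSets`, `exclusions`) and the written `paths`.
#' @export
generateStudy <- function(cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  net <- generateNetwork(cfg)
  planting <- plantAgingGenes(net, cfg)
  study <- generateExpression(net, planting, cfg)
  genes <- igraph::V(net)$name
  sets <- generateGeneSets(planting, genes, cfg)
  excl <- generateExclusionLists(planting, genes, cfg)

  paths <- list(
    network = file.path(outDir, "network.tsv"),
    expression = file.path(outDir, "expression.tsv"),
    samples = file.path(outDir, "samples.tsv"),
    positives = file.path(outDir, "positives.txt"),
    exclusions = file.path(outDir, paste0("exclusion", 1:5, ".txt")),
    gmt = file.path(outDir, "genesets.gmt"),
    manifest = file.path(outDir, "manifest.json"))

  ends <- igraph::as_edgelist(net)
  writeLines(c("# synthetic interaction network",
               paste(ends[, 1], ends[, 2], sep = "\t")), paths$network)
  writeExpression(study, paths$expression, paths$samples)
  writeGeneList(sort(setdiff(planting$planted, planting$hidden)),
                paths$positives)
  for (i in 1:5) writeGeneList(sort(excl[[i]]), paths$exclusions[i])
  writeGmt(sets, paths$gmt)
  jsonlite::write_json(list(config = unclass(cfg), seed = cfg$seed),
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(network = net, study = study, planting = planting,
                 geneSets = sets, exclusions = excl, paths = paths))
}
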