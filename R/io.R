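## Plain-text readers/writers for every on-disk artifact: TSV edge lists,
## expression matrix + sample metadata, GMT gene sets, snapshot tables and
## label files. All readers validate type invariants and report located
## errors; read/write pairs round-trip within 1e-12.

.readLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readLines(path, warn = FALSE)
}

#' Read a protein-protein interaction network from a two-column edge list
#'
#' Dialect: tab-separated `gene_a<TAB>gene_b`, `#` comment lines allowed.
#' Self-loops are dropped and duplicate (unordered) edges collapsed; the
#' counts of both are reported via [message()].
#'
#' @param path path to the edge-list TSV.
#' @return An undirected simple [igraph::igraph] with vertex names.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("# demo", "a\tb", "b\tc"), f)
#' net <- readEdgeList(f)
#' igraph::vcount(net)
readEdgeList <- function(path) {
  lines <- .readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) != 2L
  if (any(bad)) {
    stop(sprintf("edge list parse error at line %d: expected 2 tab-separated fields, got %d",
                 idx[which(bad)[1]], lengths(fields)[which(bad)[1]]),
         call. = FALSE)
  }
  if (!length(fields)) stop("empty network in ", path, call. = FALSE)
  ends <- do.call(rbind, fields)
  loops <- ends[, 1] == ends[, 2]
  ends <- ends[!loops, , drop = FALSE]
  key <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]),
               sep = "\r")
  dups <- duplicated(key)
  ends <- ends[!dups, , drop = FALSE]
  if (sum(loops) || sum(dups)) {
    message("readEdgeList: dropped ", sum(loops), " self-loop(s) and ",
            sum(dups), " duplicate edge(s)")
  }
  nodes <- sort(unique(c(ends)))
  if (!length(nodes)) stop("empty network in ", path, call. = FALSE)
  igraph::graph_from_data_frame(as.data.frame(ends),
                                directed = FALSE,
                                vertices = nodes)
}

#' Induced subgraph on the largest connected component
#'
#' Ties between equally large components are broken in favour of the
#' component containing the lexicographically smallest gene id.
#'
#' @param net undirected [igraph::igraph] with vertex names.
#' @return The induced subgraph on the winning component.
#' @export
largestComponent <- function(net) {
  stopifnot(igraph::vcount(net) > 0)
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest member id per tied component decides
    firsts <- vapply(best, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, "")
    best <- best[order(firsts)][1]
  }
  igraph::induced_subgraph(net,
    which(comp$membership == best))
}

#' Read an expression study from a matrix TSV and a sample metadata TSV
#'
#' The matrix file carries a header row of sample ids and a first column of
#' gene ids; the metadata file has columns `sample_id` and one of `age`
#' (years) or `age_group`.
#'
#' @param matrixPath expression matrix TSV.
#' @param metaPath sample metadata TSV.
#' @param mode `"intensity"` or `"counts"`.
#' @param groupOrder explicit ordering for age-group labels (default:
#'   lexicographic).
#' @return An [ExpressionStudy-class].
#' @export
readExpression <- function(matrixPath, metaPath,
                           mode = c("intensity", "counts"),
                           groupOrder = NULL) {
  mode <- match.arg(mode)
  m <- read.delim(matrixPath, check.names = FALSE,
                  colClasses = c("character"), header = TRUE)
  genes <- m[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop("duplicate gene id in ", matrixPath, ": ", dup[1], call. = FALSE)
  }
  values <- as.matrix(m[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("non-numeric expression value in ", matrixPath,
                          call. = FALSE)
  if (any(values < 0)) {
    stop("negative expression value for gene ",
         genes[which(rowSums(values < 0) > 0)[1]], call. = FALSE)
  }
  rownames(values) <- genes
  meta <- read.delim(metaPath, check.names = FALSE,
                     colClasses = "character")
  if (!"sample_id" %in% colnames(meta)) {
    stop("metadata must have a 'sample_id' column", call. = FALSE)
  }
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing)) {
    stop("sample(s) missing from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  if ("age" %in% colnames(meta)) {
    ExpressionStudy(values, age = as.numeric(meta$age), mode = mode)
  } else if ("age_group" %in% colnames(meta)) {
    ExpressionStudy(values, ageGroup = meta$age_group,
                    groupOrder = groupOrder, mode = mode)
  } else {
    stop("metadata must have an 'age' or 'age_group' column", call. = FALSE)
  }
}

#' Write an expression study to a matrix TSV and a metadata TSV
#'
#' @param study an [ExpressionStudy-class].
#' @param matrixPath,metaPath output paths.
#' @return Invisibly, the two paths.
#' @export
writeExpression <- function(study, matrixPath, metaPath) {
  v <- exprValues(study)
  df <- data.frame(gene = rownames(v), v, check.names = FALSE)
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- sampleAges(study)
  meta <- if (is.numeric(a)) {
    data.frame(sample_id = colnames(v), age = a)
  } else {
    data.frame(sample_id = colnames(v), age_group = as.character(a))
  }
  write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrixPath, metaPath))
}

#' Collapse probe-level expression to gene level via a mapping table
#'
#' Probes mapping to more than one gene symbol are removed (ambiguous
#' identifier policy), probes without a mapping are dropped, and multiple
#' probes for one gene are averaged per sample.
#'
#' @param study probe-level [ExpressionStudy-class].
#' @param mapping data frame with columns `source_id` and `gene_symbol`.
#' @return A gene-level [ExpressionStudy-class].
#' @export
mapProbes <- function(study, mapping) {
  stopifnot(all(c("source_id", "gene_symbol") %in% colnames(mapping)))
  mapping <- unique(mapping[, c("source_id", "gene_symbol")])
  nSym <- table(mapping$source_id)
  ambiguous <- names(nSym)[nSym > 1]
  mapping <- mapping[!mapping$source_id %in% ambiguous, , drop = FALSE]
  v <- exprValues(study)
  mapping <- mapping[mapping$source_id %in% rownames(v), , drop = FALSE]
  if (!nrow(mapping)) stop("no probes left after mapping", call. = FALSE)
  sub <- v[mapping$source_id, , drop = FALSE]
  collapsed <- rowsum(sub, group = mapping$gene_symbol) /
    as.vector(table(mapping$gene_symbol)[sort(unique(mapping$gene_symbol))])
  a <- sampleAges(study)
  if (is.numeric(a)) {
    ExpressionStudy(collapsed, age = a, mode = exprMode(study))
  } else {
    ExpressionStudy(collapsed, ageGroup = a, mode = exprMode(study))
  }
}

#' Bin numeric sample ages into half-open age groups
#'
#' Bins are `[lo, hi)` intervals derived from consecutive boundary pairs;
#' samples falling outside every bin are dropped. Default boundaries
#' `seq(20, 80, 10)` give the six decade groups 20-29 ... 70-79.
#'
#' @param study [ExpressionStudy-class] with numeric ages.
#' @param binEdges strictly ascending numeric boundaries (n + 1 values for n
#'   bins).
#' @return An age-group-mode [ExpressionStudy-class].
#' @export
binAges <- function(study, binEdges = seq(20, 80, 10)) {
  if (ageMode(study) != "numeric") {
    stop("binAges needs numeric sample ages", call. = FALSE)
  }
  binEdges <- as.numeric(binEdges)
  if (length(binEdges) < 2 || any(diff(binEdges) <= 0)) {
    stop("bin boundaries must be >= 2 strictly ascending values",
         call. = FALSE)
  }
  labels <- paste0(binEdges[-length(binEdges)], "-",
                   binEdges[-1] - 1)
  age <- sampleAges(study)
  idx <- findInterval(age, binEdges)        # 0 = below; length(edges) = above
  keep <- idx >= 1 & idx < length(binEdges)
  if (!any(keep)) stop("no samples fall inside the given bins", call. = FALSE)
  v <- exprValues(study)[, keep, drop = FALSE]
  grp <- factor(labels[idx[keep]], levels = labels)
  grp <- droplevels(grp)
  ExpressionStudy(v, ageGroup = grp, mode = exprMode(study))
}

#' Read / write gene-set collections in GMT format
#'
#' GMT dialect: `name<TAB>description<TAB>gene1<TAB>gene2...`, one set per
#' line. `readGmt(writeGmt(x))` is the identity.
#'
#' @param path GMT file path.
#' @return `readGmt`: a [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  lines <- .readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("GMT line ", which(short)[1], " has fewer than 3 fields",
         call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  GeneSetCollection(sets, vapply(fields, `[[`, "", 2L))
}

#' @rdname readGmt
#' @param coll a [GeneSetCollection-class].
#' @export
writeGmt <- function(coll, path) {
  sets <- geneSets(coll)
  desc <- setDescriptions(coll)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write snapshot tables
#'
#' Wide TSV with columns `gene_a`, `gene_b` and one weight column per
#' snapshot in age order; a `# dynagenet` header comment records the object
#' class and normalization scheme so that round-trips restore the object
#' type. Weights round-trip within 1e-12 relative error.
#'
#' @param x a [SnapshotSeries-class] or [DynamicSubnetwork-class].
#' @param path output TSV path.
#' @return `readSnapshots`: object of the class recorded in the header.
#' @export
writeSnapshots <- function(x, path) {
  if (is(x, "SnapshotSeries")) {
    hdr <- sprintf("# dynagenet class=SnapshotSeries scheme=%s",
                   normScheme(x))
    w <- snapshotWeights(x)
    cols <- snapshotAges(x)
    edges <- snapshotEdges(x)
  } else if (is(x, "DynamicSubnetwork")) {
    hdr <- sprintf("# dynagenet class=DynamicSubnetwork scheme=%s",
                   x@scheme)
    w <- diffWeights(x)
    cols <- diffIntervals(x)
    edges <- x@edges
  } else {
    stop("unsupported object class: ", class(x)[1], call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("gene_a", "gene_b", cols), collapse = "\t"), con)
  body <- apply(w, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(edges[, 1], edges[, 2], body, sep = "\t"), con)
  invisible(path)
}

#' @rdname writeSnapshots
#' @export
readSnapshots <- function(path) {
  lines <- .readLines(path)
  cls <- "SnapshotSeries"
  scheme <- ""
  if (grepl("^# dynagenet", lines[1])) {
    cls <- sub(".*class=(\\S+).*", "\\1", lines[1])
    scheme <- sub(".*scheme=(\\S*)\\s*$", "\\1", lines[1])
    lines <- lines[-1]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 3 || header[1] != "gene_a" || header[2] != "gene_b") {
    stop("snapshot table must start with gene_a, gene_b columns",
         call. = FALSE)
  }
  body <- fields[-1]
  bad <- lengths(body) != length(header)
  if (any(bad)) {
    stop("snapshot table line ", which(bad)[1] + 1L,
         ": expected ", length(header), " fields, got ",
         lengths(body)[which(bad)[1]], call. = FALSE)
  }
  tab <- do.call(rbind, body)
  edges <- tab[, 1:2, drop = FALSE]
  w <- matrix(as.numeric(tab[, -(1:2), drop = FALSE]), nrow = nrow(tab))
  if (anyNA(w)) stop("non-numeric snapshot weight", call. = FALSE)
  cols <- header[-(1:2)]
  if (cls == "DynamicSubnetwork") {
    new("DynamicSubnetwork", edges = edges,
        diffWeights = `colnames<-`(w, cols), intervals = cols,
        scheme = scheme)
  } else {
    SnapshotSeries(edges, w, cols, scheme = scheme)
  }
}

#' Read / write ground-truth label files
#'
#' TSV `gene<TAB>label` with label `aging` or `nonaging`.
#'
#' @param truth a [GroundTruth-class].
#' @param path TSV path.
#' @export
writeLabels <- function(truth, path) {
  df <- data.frame(
    gene = c(positives(truth), negatives(truth)),
    label = rep(c("aging", "nonaging"),
                c(length(positives(truth)), length(negatives(truth)))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  df <- read.delim(path, colClasses = "character")
  stopifnot(all(c("gene", "label") %in% colnames(df)))
  bad <- setdiff(unique(df$label), c("aging", "nonaging"))
  if (length(bad)) stop("unknown label: ", bad[1], call. = FALSE)
  GroundTruth(df$gene[df$label == "aging"], df$gene[df$label == "nonaging"])
}

#' Read / write one-gene-per-line list files
#'
#' @param path text file with one gene id per line (`#` comments allowed).
#' @export
readGeneList <- function(path) {
  lines <- .readLines(path)
  unique(lines[!grepl("^\\s*(#|$)", lines)])
}

#' @rdname readGeneList
#' @param genes character vector of gene ids.
#' @export
writeGeneList <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
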