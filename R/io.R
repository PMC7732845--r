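#' Read a protein quantification TSV
#'
#' Expects a header row of sample IDs and a first column of protein IDs.
#' Rows containing any missing value are dropped (and counted in a message);
#' non-positive values are a hard format error because log2 is taken
#' downstream.
#'
#' @param path Path to the TSV.
#' @param group_map Named character vector mapping sample ID ->
#'   `"control"`/`"case"`, or a data.frame with columns `sample`, `group`.
#' @param condition Condition tag stored in the result.
#' @return A [QuantMatrix-class].
#' @export
readQuantTSV <- function(path, group_map, condition) {
  if (!file.exists(path)) stopConfig("no such file: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopConfig("quant TSV needs an ID column and >= 1 sample")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  keep <- !apply(m, 1L, anyNA)
  logCounts(sprintf("readQuantTSV(%s): rows with missing values", basename(path)),
            nrow(m), sum(keep))
  m <- m[keep, , drop = FALSE]
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive value at protein '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  if (is.data.frame(group_map))
    group_map <- stats::setNames(as.character(group_map$group),
                                 as.character(group_map$sample))
  unknown <- setdiff(colnames(m), names(group_map))
  if (length(unknown))
    stopConfig("sample(s) not in group map: %s", paste(unknown, collapse = ", "))
  QuantMatrix(m, group_map[colnames(m)], condition)
}

#' Write a QuantMatrix (with its group map) to TSV
#'
#' @param qm A [QuantMatrix-class].
#' @param path Output TSV for the matrix.
#' @param groups_path Optional path for a two-column sample/group TSV.
#' @return `path`, invisibly.
#' @export
writeQuantTSV <- function(qm, path, groups_path = NULL) {
  m <- quantValues(qm)
  df <- data.frame(protein = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    g <- quantGroups(qm)
    write.table(data.frame(sample = names(g), group = unname(g)),
                groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, members. Duplicate members
#' within a set are collapsed (and counted); a line with fewer than three
#' fields is a format error reported with its line number.
#'
#' @param path Path to the GMT file.
#' @return Named list of unique-member character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stopConfig("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, members",
                   i, length(f)), call. = FALSE)
    members <- f[-(1:2)]
    uniq <- unique(members)
    logCounts(sprintf("readGMT set '%s': duplicate members", f[1]),
              length(members), length(uniq))
    sets[[f[1]]] <- uniq
    descs[f[1]] <- f[2]
  }
  attr(sets, "description") <- descs
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.acceptedChannels <- c("experimental", "database",
                       "transferred_experimental", "transferred_database")

#' Read a STRING-style edge table, keeping physical-binding evidence
#'
#' Keeps edges with positive evidence in at least `min_channels` of the four
#' accepted physical-binding channels (experimental, database, transferred
#' experimental, transferred database); edges supported only by other channels
#' (e.g. textmining) are dropped. Combined scores on the STRING 0-1000 integer
#' scale are divided by 1000; inputs already in [0, 1] (detected by the column
#' maximum) pass through. Duplicate undirected pairs keep the maximum
#' confidence; self-loops are removed.
#'
#' @param path Path to the TSV with columns `protein1`, `protein2`, the four
#'   channel columns, and `combined_score`.
#' @param min_channels Minimum number of accepted channels with positive
#'   evidence (default 1).
#' @return data.frame with columns `from`, `to`, the four channel columns, and
#'   `confidence` in [0, 1].
#' @export
readStringEdges <- function(path, min_channels = 1L) {
  if (!file.exists(path)) stopConfig("no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", .acceptedChannels, "combined_score")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("edge table missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  n0 <- nrow(df)
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  chan_pos <- rowSums(df[, .acceptedChannels, drop = FALSE] > 0)
  df <- df[chan_pos >= min_channels, , drop = FALSE]
  logCounts(sprintf("readStringEdges(%s): channel/self-loop filter", basename(path)),
            n0, nrow(df))
  conf <- df$combined_score
  if (length(conf) && max(conf) > 1) conf <- conf / 1000
  if (length(conf) && (any(conf < 0) || any(conf > 1)))
    stopConfig("confidence outside [0,1] after normalization")
  a <- pmin(df$protein1, df$protein2)
  b <- pmax(df$protein1, df$protein2)
  out <- data.frame(from = a, to = b,
                    df[, .acceptedChannels, drop = FALSE],
                    confidence = conf, stringsAsFactors = FALSE)
  out <- out[order(out$confidence, decreasing = TRUE), , drop = FALSE]
  dup <- duplicated(paste(out$from, out$to, sep = "\r"))
  logCounts("readStringEdges: duplicate undirected pairs", nrow(out), sum(!dup))
  out <- out[!dup, , drop = FALSE]
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an edge table for an igraph interactome in STRING-flavored TSV
#'
#' @param graph igraph with `confidence` and channel edge attributes.
#' @param path Output path.
#' @param scale1000 Write combined scores on the 0-1000 integer scale
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
writeStringEdges <- function(graph, path, scale1000 = TRUE) {
  el <- igraph::as_edgelist(graph)
  ea <- igraph::edge_attr(graph)
  conf <- ea$confidence
  df <- data.frame(protein1 = el[, 1], protein2 = el[, 2],
                   stringsAsFactors = FALSE)
  for (ch in .acceptedChannels)
    df[[ch]] <- if (!is.null(ea[[ch]])) ea[[ch]] else 0L
  df$combined_score <- if (scale1000) as.integer(round(conf * 1000)) else conf
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog-map TSV (fly gene, human gene, homology score 1-15)
#'
#' @param path Path to a TSV with columns `fly_gene`, `human_gene`, `score`.
#' @return Validated data.frame; duplicate (fly, human) pairs are an error.
#' @export
readOrthologTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("fly_gene", "human_gene", "score")
  if (!all(need %in% colnames(df)))
    stopConfig("ortholog table needs columns %s", paste(need, collapse = ", "))
  if (any(df$score < 1 | df$score > 15))
    stopConfig("homology scores must lie in [1, 15]")
  if (anyDuplicated(df[, c("fly_gene", "human_gene")]))
    stopConfig("duplicate (fly, human) ortholog pairs")
  df
}

#' Read a GWAS gene-level association TSV (human gene, p-value)
#'
#' @param path Path to a TSV with columns `human_gene`, `p`.
#' @return Validated data.frame.
#' @export
readGwasTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("human_gene", "p") %in% colnames(df)))
    stopConfig("GWAS table needs columns human_gene, p")
  if (any(df$p < 0 | df$p > 1)) stopConfig("GWAS p-values outside [0,1]")
  df
}

#' Read a single-cell reference expression TSV
#'
#' Expects a gene x cell-cluster mean-expression table (first column `gene`)
#' plus a cluster annotation TSV with columns `cluster`, `class`
#' (neuronal/glial/unannotated).
#'
#' @param expr_path Path to the expression TSV.
#' @param class_path Path to the cluster -> class TSV.
#' @return List with `expr` (matrix) and `cluster_class` (named character).
#' @export
readCellTypeRef <- function(expr_path, class_path) {
  df <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (any(m < 0)) stopConfig("reference expression must be nonnegative")
  cls <- read.delim(class_path, stringsAsFactors = FALSE)
  if (!all(c("cluster", "class") %in% colnames(cls)))
    stopConfig("cluster class table needs columns cluster, class")
  if (anyDuplicated(cls$cluster))
    stopConfig("every cluster must map to exactly one class")
  if (!all(cls$class %in% c("neuronal", "glial", "unannotated")))
    stopConfig("classes must be neuronal/glial/unannotated")
  if (!all(colnames(m) %in% cls$cluster))
    stopConfig("cluster(s) missing from class table: %s",
               paste(setdiff(colnames(m), cls$cluster), collapse = ", "))
  list(expr = m, cluster_class = stats::setNames(cls$class, cls$cluster))
}

#' Write the final comparative network as GraphML plus a flat TSV mirror
#'
#' Nodes carry the Steiner flags, cluster ID and per-condition smoothed
#' scores; edges carry confidence and affinity.
#'
#' @param graph igraph with the attributes above.
#' @param graphml_path Output GraphML path.
#' @param tsv_path Optional node-table TSV mirror.
#' @return `graphml_path`, invisibly.
#' @export
writeNetworkGraphML <- function(graph, graphml_path, tsv_path = NULL) {
  igraph::write_graph(graph, graphml_path, format = "graphml")
  if (!is.null(tsv_path)) {
    va <- igraph::vertex_attr(graph)
    write.table(as.data.frame(va, stringsAsFactors = FALSE), tsv_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(graphml_path)
}
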