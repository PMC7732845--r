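#' @import methods
#' @import stats
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom utils combn head read.delim write.table
NULL

#' QuantMatrix: protein quantification with a group design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' assay `"quant"` of strictly positive protein abundance (signal-to-noise)
#' values, a `group` column in `colData` with levels control/case, and a
#' condition tag (e.g. `"syn"` or `"tau"`) in the metadata. It is the unit of
#' differential expression.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @export
setClass("QuantMatrix", contains = "SummarizedExperiment")

setValidity("QuantMatrix", function(object) {
  msg <- character()
  if (!"quant" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'quant' is required")
  else {
    q <- SummarizedExperiment::assay(object, "quant")
    if (anyNA(q) || any(q <= 0))
      msg <- c(msg, "all quant values must be strictly positive (log2 is taken downstream)")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate protein IDs")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (!all(cd$group %in% c("control", "case")))
    msg <- c(msg, "groups must be 'control' or 'case'")
  cond <- S4Vectors::metadata(object)$condition
  if (is.null(cond) || !is.character(cond) || length(cond) != 1L)
    msg <- c(msg, "metadata()$condition must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a QuantMatrix
#'
#' @param quant Numeric matrix, proteins x samples, strictly positive, with
#'   unique rownames (protein IDs) and colnames (sample IDs).
#' @param groups Character vector (or factor) of `"control"`/`"case"`, one per
#'   column of `quant`; may be named by sample ID.
#' @param condition Single string tagging the experiment (e.g. `"syn"`).
#' @return A [QuantMatrix-class] object.
#' @export
#' @examples
#' m <- matrix(2^rnorm(12, 10), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
#' qm <- QuantMatrix(m, c("control", "control", "case", "case"), "syn")
#' quantCondition(qm)
QuantMatrix <- function(quant, groups, condition) {
  stopifnot(is.matrix(quant), !is.null(rownames(quant)), !is.null(colnames(quant)))
  groups <- stats::setNames(as.character(groups), names(groups))
  if (!is.null(names(groups))) {
    if (!all(colnames(quant) %in% names(groups)))
      stopConfig("sample(s) missing from group map: %s",
                 paste(setdiff(colnames(quant), names(groups)), collapse = ", "))
    groups <- groups[colnames(quant)]
  }
  if (length(groups) != ncol(quant))
    stopConfig("need one group per sample (%d samples, %d groups)",
               ncol(quant), length(groups))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(quant = quant),
    colData = S4Vectors::DataFrame(group = groups, row.names = colnames(quant)),
    metadata = list(condition = condition))
  new("QuantMatrix", se)
}

#' @describeIn QuantMatrix sample group assignments (character vector named by
#'   sample)
#' @param x A QuantMatrix.
#' @export
quantGroups <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$group),
                  colnames(x))
}

#' @describeIn QuantMatrix the condition tag
#' @export
quantCondition <- function(x) S4Vectors::metadata(x)$condition

#' @describeIn QuantMatrix the positive abundance matrix
#' @export
quantValues <- function(x) SummarizedExperiment::assay(x, "quant")

setMethod("show", "QuantMatrix", function(object) {
  cat(sprintf("QuantMatrix (condition '%s'): %d proteins x %d samples (%d control, %d case)\n",
              quantCondition(object), nrow(object), ncol(object),
              sum(quantGroups(object) == "control"),
              sum(quantGroups(object) == "case")))
})

#' StableNetwork: PCSF output after jitter-stability filtering
#'
#' Nodes that survived repeated prize-collecting Steiner forest solving under
#' Gaussian edge-cost jitter, with per-node detection frequency and a Steiner
#' flag (node included without carrying a prize).
#'
#' @slot nodes data.frame with columns `node`, `frequency`, `terminal`
#'   (logical), `steiner` (logical).
#' @slot condition character tag of the terminal set.
#' @slot n_runs integer, number of jittered solves.
#' @slot keep_count integer, strict detection-count threshold.
#' @export
setClass("StableNetwork",
         representation(nodes = "data.frame", condition = "character",
                        n_runs = "integer", keep_count = "integer"))

setValidity("StableNetwork", function(object) {
  nd <- object@nodes
  req <- c("node", "frequency", "terminal", "steiner")
  if (!all(req %in% colnames(nd))) return("nodes must have node/frequency/terminal/steiner")
  if (nrow(nd) && any(nd$frequency * object@n_runs <= object@keep_count))
    return("every kept node must exceed keep_count/n_runs in frequency")
  if (nrow(nd) && any(nd$steiner == nd$terminal))
    return("steiner flag must be the negation of the terminal flag")
  TRUE
})

#' @describeIn StableNetwork node table (node, frequency, terminal, steiner)
#' @param x A StableNetwork.
#' @export
stableNodes <- function(x) x@nodes

setMethod("show", "StableNetwork", function(object) {
  cat(sprintf("StableNetwork '%s': %d nodes (%d Steiner) kept at >%d/%d jittered runs\n",
              object@condition, nrow(object@nodes), sum(object@nodes$steiner),
              object@keep_count, object@n_runs))
})

#' ClusterPartition: node-to-cluster map with annotation and specificity
#'
#' The result of Louvain clustering on the pooled comparative network, with
#' per-cluster top gene-ontology annotation and a condition-specificity label
#' derived from the 30\% dysregulation rule.
#'
#' @slot membership named integer vector, node -> cluster ID (singletons
#'   already discarded).
#' @slot clusters data.frame with one row per cluster: `cluster`, `size`, and
#'   (after annotation) `term`, `p`, `fdr`, `specificity`.
#' @slot modularity numeric, weighted modularity of the selected partition at
#'   the configured resolution.
#' @export
setClass("ClusterPartition",
         representation(membership = "integer", clusters = "data.frame",
                        modularity = "numeric"))

setValidity("ClusterPartition", function(object) {
  m <- object@membership
  if (is.null(names(m))) return("membership must be named by node")
  if (length(m) && any(table(m) < 2L)) return("singleton clusters must be discarded")
  TRUE
})

#' @describeIn ClusterPartition named node->cluster vector
#' @param x A ClusterPartition.
#' @export
clusterMembership <- function(x) x@membership

#' @describeIn ClusterPartition the per-cluster summary table
#' @export
clusterTable <- function(x) x@clusters

setMethod("show", "ClusterPartition", function(object) {
  cat(sprintf("ClusterPartition: %d nodes in %d clusters (modularity %.4f)\n",
              length(object@membership), nrow(object@clusters), object@modularity))
  if ("specificity" %in% colnames(object@clusters)) {
    tab <- table(object@clusters$specificity)
    cat("  specificity:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})
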