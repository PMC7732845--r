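#' Assign genes to cell classes by maximal reference expression
#'
#' Each gene present in the single-cell reference and expressed (> 0) in at
#' least one cluster is assigned the class (neuronal/glial/unannotated) of its
#' maximal-expression cluster. Exact expression ties are broken by class
#' priority neuronal > glial > unannotated, then by cluster ID — an arbitrary
#' but deterministic convention. Genes absent from the reference or never
#' expressed are omitted and counted in `attr(, "n_unmapped")`.
#'
#' @param genes Character vector of gene IDs to assign.
#' @param reference List with `expr` (gene x cluster nonnegative matrix) and
#'   `cluster_class` (named character, cluster -> class); see
#'   [readCellTypeRef()].
#' @return Named character vector gene -> class.
#' @export
assignCellClass <- function(genes, reference) {
  expr <- reference$expr
  cls <- reference$cluster_class
  if (!all(colnames(expr) %in% names(cls)))
    stopConfig("every cluster must map to exactly one class")
  genes <- unique(genes)
  present <- intersect(genes, rownames(expr))
  prio <- c(neuronal = 1L, glial = 2L, unannotated = 3L)
  # deterministic column order: class priority then cluster ID, so which.max
  # resolves ties by that priority
  cord <- order(prio[cls[colnames(expr)]], colnames(expr))
  expr <- expr[, cord, drop = FALSE]
  sub <- expr[present, , drop = FALSE]
  expressed <- rowSums(sub) > 0
  sub <- sub[expressed, , drop = FALSE]
  out <- stats::setNames(unname(cls[colnames(sub)[max.col(sub, ties.method = "first")]]),
                         rownames(sub))
  n_unmapped <- length(genes) - length(out)
  logCounts("assignCellClass: genes assigned", length(genes), length(out))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Cell class x regulation contingency test
#'
#' Builds the 3 (neuronal/glial/unannotated) x 3 (up/down/unchanged) table
#' over mapped measured proteins — "unchanged" meaning measured, mapped, and
#' in neither significant set — and applies the Pearson chi-square test
#' (no continuity correction, df = 4, upper-tail p).
#'
#' @param assignments Named gene -> class vector from [assignCellClass()].
#' @param de_up,de_down Disjoint character vectors of significantly up- and
#'   downregulated proteins (subsets of `all_measured`).
#' @param all_measured Character vector of all measured proteins.
#' @return List with `observed`, `expected` (3x3 matrices), `statistic`, `df`,
#'   `p`, `low_expected` (TRUE when any expected cell < 1, a validity
#'   warning, not an error).
#' @export
regulationContingency <- function(assignments, de_up, de_down, all_measured) {
  if (length(intersect(de_up, de_down)))
    stopConfig("up and down sets must be disjoint")
  if (length(setdiff(c(de_up, de_down), all_measured)))
    stopConfig("significant sets must be subsets of all_measured")
  mapped <- intersect(unique(all_measured), names(assignments))
  reg <- ifelse(mapped %in% de_up, "up",
                ifelse(mapped %in% de_down, "down", "unchanged"))
  cls <- factor(unname(assignments[mapped]),
                levels = c("neuronal", "glial", "unannotated"))
  reg <- factor(reg, levels = c("up", "down", "unchanged"))
  obs <- table(class = cls, regulation = reg)
  ct <- suppressWarnings(chisq.test(obs, correct = FALSE))
  low <- any(ct$expected < 1)
  if (low)
    warning("expected cell count below 1; chi-square approximation may be unreliable",
            call. = FALSE)
  list(observed = unclass(obs), expected = ct$expected,
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, low_expected = low)
}
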