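#' Significance criterion for classifying differential expression
#'
#' @param mode `"bh_fdr"` (Benjamini-Hochberg adjusted) or `"nominal_p"`.
#' @param threshold Strict upper bound in (0, 1); a protein passes when its
#'   (adjusted) p-value is strictly below it.
#' @return List of class `"significanceCriterion"`.
#' @export
#' @examples
#' significanceCriterion("bh_fdr", 0.01)
significanceCriterion <- function(mode = c("bh_fdr", "nominal_p"),
                                  threshold = 0.05) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold >= 1)
    stopConfig("threshold must lie in (0, 1)")
  structure(list(mode = mode, threshold = threshold),
            class = "significanceCriterion")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values (monotone in p-rank).
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
bhAdjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stopConfig("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

# Welch / Student two-sample t on a single row of log2 values, with the
# degenerate zero-variance cases handled explicitly (t.test refuses
# essentially-constant data).
.rowT <- function(case, ctrl, var.equal) {
  if (var(case) == 0 && var(ctrl) == 0) {
    if (isTRUE(all.equal(mean(case), mean(ctrl))))
      return(c(t = 0, p = 1))
    return(c(t = sign(mean(case) - mean(ctrl)) * Inf, p = 0))
  }
  tt <- t.test(case, ctrl, var.equal = var.equal)
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Protein-level differential expression (two-sample t on log2 values)
#'
#' Per protein: log2 fold change = mean log2(case) - mean log2(control);
#' two-sided two-sample t-test on the log2 values (Welch by default, which is
#' the safer choice for small unequal group sizes; set `var.equal = TRUE` for
#' the pooled-variance Student variant); BH adjustment across all tested
#' proteins.
#'
#' @param quant A [QuantMatrix-class] with at least two samples per group.
#' @param var.equal Use pooled-variance Student's t instead of Welch.
#' @return data.frame with columns `protein`, `log2FC`, `t`, `p`, `q`,
#'   `direction` (`"up"`/`"down"`, sign of log2FC).
#' @export
differentialExpression <- function(quant, var.equal = FALSE) {
  stopifnot(is(quant, "QuantMatrix"))
  g <- quantGroups(quant)
  if (sum(g == "control") < 2 || sum(g == "case") < 2)
    stopConfig("need >= 2 samples per group (%d control, %d case)",
               sum(g == "control"), sum(g == "case"))
  lm2 <- log2(quantValues(quant))
  ctrl <- lm2[, g == "control", drop = FALSE]
  case <- lm2[, g == "case", drop = FALSE]
  log2FC <- rowMeans(case) - rowMeans(ctrl)
  tp <- t(vapply(seq_len(nrow(lm2)),
                 function(i) .rowT(case[i, ], ctrl[i, ], var.equal),
                 c(t = 0, p = 0)))
  data.frame(protein = rownames(lm2),
             log2FC = unname(log2FC),
             t = tp[, "t"], p = tp[, "p"], q = bhAdjust(tp[, "p"]),
             direction = ifelse(log2FC >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split a DE table into significant up / down sets
#'
#' Strict inequality against the criterion threshold; passing proteins with
#' exactly zero log2 fold change (a measure-zero event) are assigned to
#' neither set and counted in a message.
#'
#' @param de DE table from [differentialExpression()].
#' @param criterion A [significanceCriterion()].
#' @return List with character vectors `up` and `down`.
#' @export
classifySignificant <- function(de, criterion) {
  stopifnot(inherits(criterion, "significanceCriterion"))
  if (!nrow(de)) return(list(up = character(), down = character()))
  val <- if (criterion$mode == "bh_fdr") de$q else de$p
  pass <- val < criterion$threshold
  zero <- pass & de$log2FC == 0
  if (any(zero))
    message(sprintf("[pcsfCompare] classifySignificant: %d passing protein(s) with log2FC == 0 assigned to neither set",
                    sum(zero)))
  list(up = de$protein[pass & de$log2FC > 0],
       down = de$protein[pass & de$log2FC < 0])
}

#' Z-score transform and average-linkage correlation clustering
#'
#' Rows (proteins) are z-scored to mean 0, SD 1; agglomerative clustering with
#' distance 1 - Pearson correlation and average linkage is applied to both
#' proteins and samples, as used for supervised heatmaps of significant
#' proteins. Constant rows, whose correlations are undefined, are dropped with
#' a count.
#'
#' @param quant A [QuantMatrix-class].
#' @param proteins Optional protein subset (default all).
#' @return List with `zmat` (z-scored matrix), `row_hclust`, `col_hclust`,
#'   `row_order`, `col_order` (dendrogram leaf orders).
#' @export
zscoreCluster <- function(quant, proteins = NULL) {
  m <- quantValues(quant)
  if (!is.null(proteins)) {
    miss <- setdiff(proteins, rownames(m))
    if (length(miss)) stopConfig("unknown protein(s): %s", paste(head(miss, 3), collapse = ", "))
    m <- m[proteins, , drop = FALSE]
  }
  sds <- apply(m, 1L, sd)
  logCounts("zscoreCluster: constant rows", nrow(m), sum(sds > 0))
  m <- m[sds > 0, , drop = FALSE]
  if (nrow(m) < 2) stopConfig("need >= 2 non-constant proteins to cluster")
  z <- t(scale(t(m)))
  dr <- as.dist(1 - cor(t(z)))
  dc <- as.dist(1 - cor(z))
  hr <- hclust(dr, method = "average")
  hc <- hclust(dc, method = "average")
  list(zmat = z, row_hclust = hr, col_hclust = hc,
       row_order = rownames(z)[hr$order], col_order = colnames(z)[hc$order])
}
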