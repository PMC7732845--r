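#' Map fly genes to human orthologs above a homology-score floor
#'
#' For each input fly gene, all human orthologs with integrated homology score
#' >= `min_score` are retained; per fly gene, the best-scoring ortholog is
#' flagged (score ties broken by human gene ID). Output is sorted by score
#' descending then gene IDs, so a head of the table reproduces a
#' "top N by homology score" display list.
#'
#' @param fly_genes Character vector of fly gene IDs.
#' @param map Ortholog table (see [readOrthologTSV()]): `fly_gene`,
#'   `human_gene`, `score` in [1, 15].
#' @param min_score Minimum homology score to keep a pair.
#' @return data.frame `fly_gene`, `human_gene`, `score`, `best` (logical);
#'   unmapped fly genes in `attr(, "unmapped")`.
#' @export
mapOrthologs <- function(fly_genes, map, min_score = 1L) {
  stopifnot(all(c("fly_gene", "human_gene", "score") %in% colnames(map)))
  fly_genes <- unique(fly_genes)
  hit <- map[map$fly_gene %in% fly_genes & map$score >= min_score, , drop = FALSE]
  hit <- hit[order(-hit$score, hit$fly_gene, hit$human_gene), , drop = FALSE]
  best_idx <- !duplicated(hit$fly_gene)
  out <- data.frame(fly_gene = hit$fly_gene, human_gene = hit$human_gene,
                    score = hit$score, best = best_idx,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  unmapped <- setdiff(fly_genes, out$fly_gene)
  logCounts("mapOrthologs: fly genes with a retained ortholog",
            length(fly_genes), length(fly_genes) - length(unmapped))
  attr(out, "unmapped") <- sort(unmapped)
  out
}

#' Intersect ortholog pairs with GWAS gene-level associations
#'
#' Keeps ortholog pairs whose human gene has a GWAS gene-level p-value strictly
#' below `p_cutoff`. The cutoff has no default on purpose: the caller must
#' state the significance convention used. Human genes absent from the GWAS
#' table are excluded with a count, not an error.
#'
#' @param pairs Output of [mapOrthologs()] (optionally carrying extra columns
#'   such as the fly DE direction).
#' @param gwas GWAS table (see [readGwasTSV()]): `human_gene`, `p`.
#' @param p_cutoff Strict GWAS p-value cutoff; required.
#' @return data.frame of retained pairs with `gwas_p` appended, sorted by
#'   `gwas_p` then gene IDs (deterministic in input row order).
#' @export
intersectGwas <- function(pairs, gwas, p_cutoff) {
  if (missing(p_cutoff)) stopConfig("p_cutoff must be given explicitly")
  stopifnot(all(c("human_gene", "p") %in% colnames(gwas)))
  idx <- match(pairs$human_gene, gwas$human_gene)
  known <- !is.na(idx)
  logCounts("intersectGwas: pairs with a GWAS entry", nrow(pairs), sum(known))
  out <- pairs[known, , drop = FALSE]
  out$gwas_p <- gwas$p[idx[known]]
  out <- out[out$gwas_p < p_cutoff, , drop = FALSE]
  out <- out[order(out$gwas_p, out$fly_gene, out$human_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
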