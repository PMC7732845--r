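#' Enrichment analysis configuration
#'
#' @param z_cutoff Z-score cutoff for over-representation calls (default 2).
#' @param ora_fdr BH-FDR cutoff for pathway over-representation (default 0.05).
#' @param gsea_size Size bounds for preranked GSEA sets after background
#'   intersection (default c(10, 100)).
#' @param annotation_size Size bounds for cluster-annotation terms
#'   (default c(5, 50)).
#' @param permutations GSEA null permutation count (default 1000), or
#'   `"exhaustive"` to enumerate every same-size set (tiny backgrounds only).
#' @param seed Seed for the GSEA permutation null.
#' @return List of class `"enrichmentConfig"`.
#' @export
enrichmentConfig <- function(z_cutoff = 2, ora_fdr = 0.05,
                             gsea_size = c(10L, 100L),
                             annotation_size = c(5L, 50L),
                             permutations = 1000L, seed = 1L) {
  for (b in list(gsea_size, annotation_size))
    if (length(b) != 2 || any(b <= 0) || b[1] >= b[2])
      stopConfig("size bounds must be positive with min < max")
  structure(list(z_cutoff = z_cutoff, ora_fdr = ora_fdr,
                 gsea_size = as.integer(gsea_size),
                 annotation_size = as.integer(annotation_size),
                 permutations = permutations, seed = as.integer(seed)),
            class = "enrichmentConfig")
}

.oraCounts <- function(input_set, term_set, background) {
  background <- unique(background)
  input_set <- unique(input_set)
  if (!length(background)) stopConfig("empty background")
  if (length(setdiff(input_set, background)))
    stopConfig("input set must be a subset of the background")
  term_set <- intersect(unique(term_set), background)
  list(r = length(intersect(input_set, term_set)),
       R = length(term_set), n = length(input_set), N = length(background))
}

#' One-sided Fisher (hypergeometric upper-tail) over-representation test
#'
#' p = P(X >= r) where X is hypergeometric with `R` term genes among `N`
#' background genes, drawing `n` input genes. The term set is intersected with
#' the background before testing.
#'
#' @param input_set Character vector of input genes (subset of background).
#' @param term_set Character vector of term genes.
#' @param background Character vector of background genes.
#' @return One-row data.frame with `r`, `R`, `n`, `N`, `p`.
#' @export
#' @examples
#' oraFisher(letters[1:5], letters[1:5], letters[1:20])$p  # 1 / choose(20, 5)
oraFisher <- function(input_set, term_set, background) {
  cc <- .oraCounts(input_set, term_set, background)
  p <- phyper(cc$r - 1, cc$R, cc$N - cc$R, cc$n, lower.tail = FALSE)
  data.frame(r = cc$r, R = cc$R, n = cc$n, N = cc$N, p = p)
}

#' Z-score over-representation statistic
#'
#' The normal approximation to the hypergeometric with finite-population
#' correction, as used by GO-Elite-style enrichment with a z = 2 call cutoff:
#' z = (r - nR/N) / sqrt(n (R/N) (1 - R/N) (1 - (n-1)/(N-1))).
#'
#' @inheritParams oraFisher
#' @return One-row data.frame with `r`, `R`, `n`, `N`, `z`.
#' @export
oraZscore <- function(input_set, term_set, background) {
  cc <- .oraCounts(input_set, term_set, background)
  if (cc$N <= 1) stopConfig("z undefined for background of size <= 1")
  f <- cc$R / cc$N
  denom <- sqrt(cc$n * f * (1 - f) * (1 - (cc$n - 1) / (cc$N - 1)))
  if (denom == 0) stopConfig("degenerate z denominator (R = 0, R = N or n = N)")
  data.frame(r = cc$r, R = cc$R, n = cc$n, N = cc$N,
             z = (cc$r - cc$n * f) / denom)
}

#' Over-representation analysis across a gene-set collection
#'
#' Applies [oraFisher()] (and [oraZscore()]) to every set, with BH adjustment
#' across terms through the same step-up implementation used for differential
#' expression.
#'
#' @param input_set Character vector of input genes.
#' @param gene_sets Named list of gene sets.
#' @param background Background gene universe.
#' @param size_bounds Optional c(min, max) set-size filter applied after
#'   background intersection.
#' @return data.frame with one row per tested term: `term`, `r`, `R`, `n`,
#'   `N`, `z`, `p`, `q`.
#' @export
oraTable <- function(input_set, gene_sets, background, size_bounds = NULL) {
  sizes <- vapply(gene_sets, function(s)
    length(intersect(unique(s), unique(background))), integer(1))
  keep <- rep(TRUE, length(gene_sets))
  if (!is.null(size_bounds))
    keep <- sizes >= size_bounds[1] & sizes <= size_bounds[2]
  logCounts("oraTable: size-filtered terms", length(gene_sets), sum(keep))
  gs <- gene_sets[keep]
  if (!length(gs))
    return(data.frame(term = character(), r = integer(), R = integer(),
                      n = integer(), N = integer(), z = numeric(),
                      p = numeric(), q = numeric()))
  rows <- lapply(names(gs), function(nm) {
    fr <- oraFisher(input_set, gs[[nm]], background)
    z <- tryCatch(oraZscore(input_set, gs[[nm]], background)$z,
                  error = function(e) NA_real_)
    cbind(data.frame(term = nm, stringsAsFactors = FALSE), fr, z = z)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out[order(out$p, out$term), c("term", "r", "R", "n", "N", "z", "p", "q")]
}

# Weighted (exponent 1) Kolmogorov-Smirnov running-sum enrichment score for a
# hit indicator over a ranked list. Hits increment by |score|/sum(|score| over
# hits); misses decrement by 1/(N - N_hits). ES is the signed maximum
# deviation of the running sum.
.gseaES <- function(scores_sorted, hit) {
  n <- length(scores_sorted)
  nh <- sum(hit)
  if (nh == 0 || nh == n) return(0)
  w <- abs(scores_sorted)
  sh <- sum(w[hit])
  step <- ifelse(hit,
                 if (sh > 0) w / sh else 1 / nh,  # all-zero hit scores: uniform
                 -1 / (n - nh))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment (weighted KS running sum)
#'
#' Genes are ranked by signed score (descending; ties broken by gene ID so the
#' ranking is deterministic). For each set intersected with the ranked
#' background and inside the configured size bounds, the enrichment score is
#' the signed maximum of the weighted Kolmogorov-Smirnov running sum (weight
#' exponent 1). The nominal p-value is the tail probability of the ES under a
#' null of random same-size gene sets — Monte Carlo with
#' `config$permutations` draws (add-one corrected), or the full enumeration of
#' all same-size subsets when `config$permutations == "exhaustive"`.
#'
#' @param ranked Named numeric vector, gene -> signed score; no duplicate
#'   names.
#' @param gene_sets Named list of gene sets.
#' @param config An [enrichmentConfig()].
#' @return data.frame with `term`, `size` (after intersection), `ES`, `p`.
#' @export
gseaPrerank <- function(ranked, gene_sets, config = enrichmentConfig()) {
  if (anyDuplicated(names(ranked))) stopConfig("duplicate genes in ranked list")
  ord <- order(-ranked, names(ranked))
  scores <- unname(ranked[ord])
  genes <- names(ranked)[ord]
  n <- length(genes)
  sizes <- vapply(gene_sets, function(s) length(intersect(unique(s), genes)),
                  integer(1))
  keep <- sizes >= config$gsea_size[1] & sizes <= config$gsea_size[2]
  logCounts("gseaPrerank: size-filtered sets", length(gene_sets), sum(keep))
  gs <- gene_sets[keep]
  if (!length(gs))
    return(data.frame(term = character(), size = integer(), ES = numeric(),
                      p = numeric()))
  exhaustive <- identical(config$permutations, "exhaustive")
  res <- withSeed(stageSeed(config$seed, "gsea"), {
    lapply(names(gs), function(nm) {
      hit <- genes %in% gs[[nm]]
      k <- sum(hit)
      es <- .gseaES(scores, hit)
      if (exhaustive) {
        combos <- combn(n, k)
        null_es <- apply(combos, 2L, function(idx) {
          h <- logical(n); h[idx] <- TRUE
          .gseaES(scores, h)
        })
        p <- if (es >= 0) mean(null_es >= es) else mean(null_es <= es)
      } else {
        nperm <- as.integer(config$permutations)
        null_es <- vapply(seq_len(nperm), function(i) {
          h <- logical(n); h[sample.int(n, k)] <- TRUE
          .gseaES(scores, h)
        }, numeric(1))
        hits <- if (es >= 0) sum(null_es >= es) else sum(null_es <= es)
        p <- (1 + hits) / (1 + nperm)
      }
      data.frame(term = nm, size = k, ES = es, p = p, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
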