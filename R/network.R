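#' Build an interactome graph from a filtered edge table
#'
#' Simple undirected graph (self-loops and duplicate edges removed, maximum
#' confidence kept) restricted to its largest connected component.
#'
#' @param edge_table data.frame from [readStringEdges()] (columns `from`,
#'   `to`, `confidence`, plus optional channel flags carried as edge
#'   attributes).
#' @return igraph with edge attribute `confidence`.
#' @export
buildInteractome <- function(edge_table) {
  if (!nrow(edge_table)) stopConfig("empty edge table after filtering")
  g <- igraph::graph_from_data_frame(edge_table, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(confidence = "max", "first"))
  comps <- igraph::components(g)
  keep <- which(comps$membership == which.max(comps$csize))
  logCounts("buildInteractome: largest connected component",
            igraph::vcount(g), length(keep))
  igraph::induced_subgraph(g, keep)
}

#' Build a terminal (prize) set from a DE table
#'
#' Terminals are proteins dysregulated at BH FDR strictly below `fdr_cutoff`
#' and present in the interactome. Weights are |log2FC| clipped to `clip`;
#' prizes are `beta` times the weight. Zero-weight terminals (exactly zero
#' fold change) are dropped with a count.
#'
#' @param de DE table from [differentialExpression()].
#' @param interactome igraph; terminals outside it are dropped with a count.
#' @param fdr_cutoff Strict FDR threshold (default 0.1).
#' @param clip Clip bound on |log2FC| (default 1).
#' @param beta Prize scaling (default 2).
#' @param condition Condition tag; defaults to `"de"`.
#' @return List of class `"terminalSet"` with `prizes` (named, in (0, beta *
#'   clip]), `weights` (named, in (0, clip]), `condition`.
#' @export
#' @examples
#' de <- data.frame(protein = c("a", "b"), log2FC = c(3, -0.5),
#'                  t = c(5, -4), p = c(1e-4, 1e-3), q = c(0.01, 0.05),
#'                  direction = c("up", "down"))
#' g <- igraph::make_graph(~ a - b)
#' makeTerminals(de, g)$prizes  # a: 2, b: 1
makeTerminals <- function(de, interactome, fdr_cutoff = 0.1, clip = 1,
                          beta = 2, condition = "de") {
  sig <- de[de$q < fdr_cutoff, , drop = FALSE]
  ing <- sig$protein %in% igraph::V(interactome)$name
  logCounts(sprintf("makeTerminals(%s): terminals present in interactome", condition),
            nrow(sig), sum(ing))
  sig <- sig[ing, , drop = FALSE]
  w <- pmin(abs(sig$log2FC), clip)
  nz <- w > 0
  logCounts(sprintf("makeTerminals(%s): nonzero weights", condition),
            length(w), sum(nz))
  structure(list(prizes = stats::setNames(beta * w[nz], sig$protein[nz]),
                 weights = stats::setNames(w[nz], sig$protein[nz]),
                 condition = condition, fdr_cutoff = fdr_cutoff),
            class = "terminalSet")
}

#' Pool per-condition stable networks into the comparative graph
#'
#' Union of the stable node sets, induced subgraph of the interactome, trimmed
#' to the largest connected component. Node attributes record the origin
#' (`"syn"`, `"tau"`, `"both"`) and per-condition Steiner status.
#'
#' @param stable_syn,stable_tau [StableNetwork-class] objects.
#' @param interactome igraph the stable networks were computed on.
#' @return igraph with vertex attributes `origin`, `steiner_syn`,
#'   `steiner_tau`, and the inherited `confidence` edge attribute.
#' @export
poolNetworks <- function(stable_syn, stable_tau, interactome) {
  ns <- stableNodes(stable_syn); nt <- stableNodes(stable_tau)
  pool <- union(ns$node, nt$node)
  if (!length(pool)) stopConfig("empty pooled node set")
  g <- igraph::induced_subgraph(interactome,
                                intersect(pool, igraph::V(interactome)$name))
  comps <- igraph::components(g)
  keep <- which(comps$membership == which.max(comps$csize))
  logCounts("poolNetworks: largest connected component", igraph::vcount(g),
            length(keep))
  g <- igraph::induced_subgraph(g, keep)
  vn <- igraph::V(g)$name
  in_syn <- vn %in% ns$node; in_tau <- vn %in% nt$node
  igraph::V(g)$origin <- ifelse(in_syn & in_tau, "both",
                                ifelse(in_syn, stable_syn@condition,
                                       stable_tau@condition))
  igraph::V(g)$steiner_syn <- vn %in% ns$node[ns$steiner]
  igraph::V(g)$steiner_tau <- vn %in% nt$node[nt$steiner]
  g
}

#' Smoothing (personalized PageRank) configuration
#'
#' @param alpha PageRank damping in (0, 1); default 0.85.
#' @return List of class `"smoothingConfig"`.
#' @export
smoothingConfig <- function(alpha = 0.85) {
  if (alpha <= 0 || alpha >= 1) stopConfig("alpha must lie in (0, 1)")
  structure(list(alpha = alpha), class = "smoothingConfig")
}

#' Clustering (Louvain) configuration
#'
#' @param gamma_res Modularity resolution (> 0); default 4.
#' @param n_init Number of random initializations; the best-modularity
#'   partition is kept (default 100).
#' @param seed Integer seed.
#' @return List of class `"clusteringConfig"`.
#' @export
clusteringConfig <- function(gamma_res = 4, n_init = 100L, seed = 1L) {
  if (gamma_res <= 0) stopConfig("gamma_res must be > 0")
  structure(list(gamma_res = gamma_res, n_init = as.integer(n_init),
                 seed = as.integer(seed)), class = "clusteringConfig")
}

#' Personalized-PageRank smoothing of per-condition prize weights
#'
#' For each condition, standard personalized PageRank with damping `alpha` is
#' run on the confidence-weighted pooled graph with the condition's prize
#' weights (restricted to pooled nodes and renormalized to sum 1) as the
#' personalization vector; a condition with zero mass on the pooled graph
#' falls back to the uniform personalization with a message. Each smoothed
#' vector is a probability distribution (sums to 1).
#'
#' @param pooled igraph from [poolNetworks()] with `confidence` edge weights.
#' @param prize_list Named list of named prize/weight vectors, one per
#'   condition (e.g. `list(syn = ..., tau = ...)`).
#' @param config A [smoothingConfig()].
#' @return Numeric matrix, nodes x conditions, each column summing to 1.
#' @export
pagerankSmooth <- function(pooled, prize_list, config = smoothingConfig()) {
  stopifnot(inherits(config, "smoothingConfig"))
  vn <- igraph::V(pooled)$name
  out <- sapply(names(prize_list), function(cond) {
    w <- prize_list[[cond]]
    pers <- stats::setNames(numeric(length(vn)), vn)
    common <- intersect(names(w), vn)
    pers[common] <- w[common]
    if (sum(pers) <= 0) {
      message(sprintf("[pcsfCompare] pagerankSmooth: no '%s' prize mass on pooled graph; uniform personalization",
                      cond))
      pers[] <- 1
    }
    igraph::page_rank(pooled, damping = config$alpha,
                      personalized = pers / sum(pers),
                      weights = igraph::E(pooled)$confidence)$vector
  })
  rownames(out) <- vn
  out
}

#' Cosine affinity of edge endpoints' smoothed score vectors
#'
#' affinity(u, v) = x_u . x_v / (|x_u| |x_v|), approaching 1 when both
#' endpoints show the same cross-condition pattern of (absolute) smoothed
#' dysregulation and 0 when the patterns are orthogonal. A zero-norm endpoint
#' yields affinity 0 with a message.
#'
#' @param pooled igraph from [poolNetworks()].
#' @param smoothed Node x condition matrix from [pagerankSmooth()].
#' @return Numeric vector of per-edge affinities in [0, 1] (nonnegative
#'   inputs), in `igraph::E(pooled)` order.
#' @export
edgeAffinity <- function(pooled, smoothed) {
  el <- igraph::ends(pooled, igraph::E(pooled), names = TRUE)
  x <- smoothed[el[, 1], , drop = FALSE]
  y <- smoothed[el[, 2], , drop = FALSE]
  nx <- sqrt(rowSums(x^2)); ny <- sqrt(rowSums(y^2))
  aff <- rowSums(x * y) / (nx * ny)
  zero <- nx == 0 | ny == 0
  if (any(zero)) {
    message(sprintf("[pcsfCompare] edgeAffinity: %d edge(s) with a zero-norm endpoint set to affinity 0",
                    sum(zero)))
    aff[zero] <- 0
  }
  pmin(pmax(aff, 0), 1)
}

# canonical signature of a partition for deterministic tie-breaks: cluster IDs
# relabeled in order of first appearance over sorted node names.
.partitionSignature <- function(membership) {
  m <- membership[order(names(membership))]
  paste(match(m, unique(m)), collapse = ",")
}

#' Louvain clustering on affinity weights, best of n random initializations
#'
#' Weighted Louvain community detection at modularity resolution
#' `config$gamma_res`; the partition with the best modularity over
#' `config$n_init` seeded initializations is selected (modularity ties broken
#' by lexicographically smallest canonical partition signature). Singleton
#' clusters are discarded with a count.
#'
#' @param pooled igraph from [poolNetworks()].
#' @param affinity Per-edge weights from [edgeAffinity()].
#' @param config A [clusteringConfig()].
#' @return A [ClusterPartition-class] (annotation columns filled by
#'   [annotateAndLabel()]).
#' @export
louvainCluster <- function(pooled, affinity, config = clusteringConfig()) {
  stopifnot(inherits(config, "clusteringConfig"))
  if (length(affinity) != igraph::ecount(pooled))
    stopConfig("need one affinity per edge")
  if (!any(affinity > 0))
    stopConfig("no positive-weight edge; clustering undefined")
  best <- NULL
  withSeed(stageSeed(config$seed, "louvain"), {
    for (i in seq_len(config$n_init)) {
      cl <- igraph::cluster_louvain(pooled, weights = affinity,
                                    resolution = config$gamma_res)
      mem <- stats::setNames(igraph::membership(cl), igraph::V(pooled)$name)
      q <- igraph::modularity(pooled, mem, weights = affinity,
                              resolution = config$gamma_res)
      sig <- .partitionSignature(mem)
      if (is.null(best) || q > best$q + 1e-12 ||
          (abs(q - best$q) <= 1e-12 && sig < best$sig)) {
        best <- list(q = q, mem = mem, sig = sig)
      }
    }
  })
  mem <- best$mem
  sizes <- table(mem)
  single <- names(sizes)[sizes < 2]
  logCounts("louvainCluster: nodes in non-singleton clusters",
            length(mem), sum(!mem %in% as.integer(single)))
  mem <- mem[!mem %in% as.integer(single)]
  relab <- stats::setNames(seq_along(unique(mem)), sort(unique(mem)))
  mem <- stats::setNames(as.integer(relab[as.character(mem)]), names(mem))
  cl_tab <- as.data.frame(table(cluster = mem), stringsAsFactors = FALSE)
  clusters <- data.frame(cluster = as.integer(cl_tab$cluster),
                         size = as.integer(cl_tab$Freq))
  new("ClusterPartition", membership = mem, clusters = clusters,
      modularity = best$q)
}

#' Annotate clusters with their most-enriched term and specificity label
#'
#' Each cluster is annotated with its lowest-p term by one-sided Fisher's
#' exact test against the interactome background, over terms with between
#' `config$annotation_size[1]` and `config$annotation_size[2]` background
#' members; BH adjustment is applied across all cluster x term tests. Ties are
#' broken by smaller term size then term ID. A cluster is labeled dysregulated
#' for a condition when strictly more than `label_fraction` of its nodes have
#' FDR < `fdr_cutoff` in that condition; the specificity label is `"syn"`,
#' `"tau"`, `"both"` or `"neither"` accordingly.
#'
#' @param partition A [ClusterPartition-class].
#' @param gene_sets Named list of gene sets.
#' @param de_syn,de_tau DE tables for the two conditions.
#' @param background Character vector: the interactome node universe.
#' @param config An [enrichmentConfig()].
#' @param fdr_cutoff Per-node dysregulation FDR threshold (default 0.1).
#' @param label_fraction Strict node-fraction threshold for labeling
#'   (default 0.3).
#' @return The partition with `term`, `p`, `fdr`, `specificity` columns filled
#'   in its cluster table; the full cluster x term test table in
#'   `attr(clusterTable(x), "tests")`.
#' @export
annotateAndLabel <- function(partition, gene_sets, de_syn, de_tau, background,
                             config = enrichmentConfig(), fdr_cutoff = 0.1,
                             label_fraction = 0.3) {
  stopifnot(is(partition, "ClusterPartition"))
  background <- unique(background)
  sizes <- vapply(gene_sets, function(s) length(intersect(unique(s), background)),
                  integer(1))
  keep <- sizes >= config$annotation_size[1] & sizes <= config$annotation_size[2]
  logCounts("annotateAndLabel: size-filtered terms", length(gene_sets), sum(keep))
  gs <- gene_sets[keep]
  mem <- clusterMembership(partition)
  cl_ids <- sort(unique(mem))
  tests <- list()
  for (cid in cl_ids) {
    members <- intersect(names(mem)[mem == cid], background)
    for (nm in names(gs)) {
      fr <- oraFisher(members, gs[[nm]], background)
      tests[[length(tests) + 1L]] <- cbind(
        data.frame(cluster = cid, term = nm, stringsAsFactors = FALSE), fr)
    }
  }
  tt <- if (length(tests)) do.call(rbind, tests) else
    data.frame(cluster = integer(), term = character(), r = integer(),
               R = integer(), n = integer(), N = integer(), p = numeric())
  tt$fdr <- if (nrow(tt)) bhAdjust(tt$p) else numeric()

  dys <- function(de) de$protein[de$q < fdr_cutoff]
  dsyn <- dys(de_syn); dtau <- dys(de_tau)
  ct <- clusterTable(partition)
  ct$term <- NA_character_; ct$p <- NA_real_; ct$fdr <- NA_real_
  ct$frac_syn <- NA_real_; ct$frac_tau <- NA_real_
  ct$specificity <- NA_character_
  for (i in seq_len(nrow(ct))) {
    cid <- ct$cluster[i]
    sub <- tt[tt$cluster == cid, , drop = FALSE]
    if (nrow(sub)) {
      sub <- sub[order(sub$p, sub$R, sub$term), , drop = FALSE]
      ct$term[i] <- sub$term[1]; ct$p[i] <- sub$p[1]; ct$fdr[i] <- sub$fdr[1]
    } else {
      ct$term[i] <- "unannotated"
      message(sprintf("[pcsfCompare] annotateAndLabel: cluster %d has no testable term", cid))
    }
    members <- names(mem)[mem == cid]
    fs <- mean(members %in% dsyn); ft <- mean(members %in% dtau)
    ct$frac_syn[i] <- fs; ct$frac_tau[i] <- ft
    syn_lab <- fs > label_fraction; tau_lab <- ft > label_fraction
    ct$specificity[i] <- if (syn_lab && tau_lab) "both"
      else if (syn_lab) "syn" else if (tau_lab) "tau" else "neither"
  }
  attr(ct, "tests") <- tt
  methods::initialize(partition, clusters = ct)
}

#' Two-condition overlap counts and Fisher tests
#'
#' Per direction (up/down at the given criterion), the overlap of the two
#' conditions' significant sets over the shared background (proteins detected
#' in either experiment), with a two-sided Fisher exact test on the 2x2
#' in/out table.
#'
#' @param de_syn,de_tau DE tables.
#' @param background Character vector of background proteins; both conditions'
#'   significant sets are intersected with it.
#' @param criterion A [significanceCriterion()]; default nominal p < 0.05 as
#'   used for Venn-style overlap displays.
#' @return data.frame with one row per direction: `direction`, `n_syn`,
#'   `n_tau`, `overlap`, `background`, `p`.
#' @export
compareOverlap <- function(de_syn, de_tau, background,
                           criterion = significanceCriterion("nominal_p", 0.05)) {
  background <- unique(background)
  if (!length(background)) stopConfig("empty background")
  s <- classifySignificant(de_syn, criterion)
  t_ <- classifySignificant(de_tau, criterion)
  one <- function(a, b, dirn) {
    a <- intersect(a, background); b <- intersect(b, background)
    r <- length(intersect(a, b)); N <- length(background)
    tab <- matrix(c(r, length(a) - r, length(b) - r,
                    N - length(a) - length(b) + r), 2, 2)
    data.frame(direction = dirn, n_syn = length(a), n_tau = length(b),
               overlap = r, background = N,
               p = fisher.test(tab)$p.value, stringsAsFactors = FALSE)
  }
  rbind(one(s$up, t_$up, "up"), one(s$down, t_$down, "down"))
}
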