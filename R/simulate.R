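#' Simulation configuration for the synthetic benchmark
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' benchmark conditions: a ~300-node scale-free interactome with seven planted
#' dysregulation modules covering all five condition patterns, a planted log2
#' effect of 1.0 with log2 noise SD 0.3, and a 5-control vs 6-case design per
#' condition.
#'
#' @param n_nodes Number of interactome nodes (>= 10).
#' @param edge_model `"scale-free"` (preferential attachment) or
#'   `"configuration"` (Poisson degree sequence).
#' @param mean_degree Target mean degree.
#' @param n_modules Number of planted modules.
#' @param module_sizes Integer vector of module sizes (each >= 3, sum <= n_nodes).
#' @param module_patterns Character vector over
#'   `c("syn_only_up","syn_only_down","tau_only","shared_same","shared_opposite")`,
#'   length `n_modules`.
#' @param module_degree Target mean internal degree of a planted module;
#'   planting adds within-module edges (protein complexes are locally dense,
#'   unlike the tree-like neighborhoods of preferential-attachment graphs)
#'   until each module's induced subgraph reaches it.
#' @param effect_size Planted log2 fold change magnitude.
#' @param noise_sd Log2-scale Gaussian noise SD (> 0).
#' @param n_control,n_case Samples per group.
#' @param ortholog_fraction Fraction of nodes given a synthetic human ortholog.
#' @param n_gwas_enriched Number of mapped planted genes given enriched (low)
#'   GWAS p-values.
#' @param n_decoy_sets Number of decoy gene sets in the synthetic GMT.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A validated list of class `"simConfig"`.
#' @export
#' @examples
#' cfg <- simConfig(n_nodes = 100, seed = 7)
#' cfg$mean_degree
simConfig <- function(n_nodes = 300L,
                      edge_model = c("scale-free", "configuration"),
                      mean_degree = 6,
                      n_modules = 7L,
                      module_sizes = c(12L, 10L, 10L, 8L, 8L, 7L, 6L),
                      module_patterns = c("syn_only_up", "syn_only_down",
                                          "tau_only", "shared_same",
                                          "shared_opposite", "syn_only_up",
                                          "shared_same"),
                      module_degree = 4,
                      effect_size = 1.0,
                      noise_sd = 0.3,
                      n_control = 5L,
                      n_case = 6L,
                      ortholog_fraction = 0.7,
                      n_gwas_enriched = 10L,
                      n_decoy_sets = 15L,
                      seed = 1L) {
  edge_model <- match.arg(edge_model)
  patterns <- c("syn_only_up", "syn_only_down", "tau_only",
                "shared_same", "shared_opposite")
  if (!is.numeric(n_nodes) || n_nodes <= 0)
    stopConfig("n_nodes must be a positive count")
  if (n_nodes < 10) stopConfig("n_nodes must be >= 10")
  if (noise_sd <= 0) stopConfig("noise_sd must be > 0")
  if (mean_degree <= 0) stopConfig("mean_degree must be > 0")
  if (length(module_sizes) != n_modules || length(module_patterns) != n_modules)
    stopConfig("module_sizes and module_patterns must have length n_modules")
  if (any(module_sizes < 3)) stopConfig("module sizes must be >= 3")
  if (sum(module_sizes) > n_nodes) stopConfig("sum(module_sizes) exceeds n_nodes")
  if (!all(module_patterns %in% patterns))
    stopConfig("unknown module pattern(s): %s",
               paste(setdiff(module_patterns, patterns), collapse = ", "))
  if (n_control < 2 || n_case < 2) stopConfig("need >= 2 samples per group")
  structure(list(n_nodes = as.integer(n_nodes), edge_model = edge_model,
                 mean_degree = mean_degree, n_modules = as.integer(n_modules),
                 module_sizes = as.integer(module_sizes),
                 module_patterns = module_patterns,
                 module_degree = module_degree,
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_control = as.integer(n_control), n_case = as.integer(n_case),
                 ortholog_fraction = ortholog_fraction,
                 n_gwas_enriched = as.integer(n_gwas_enriched),
                 n_decoy_sets = as.integer(n_decoy_sets),
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Simulate a confidence-weighted protein interactome
#'
#' Generates an undirected simple connected graph (largest component retained)
#' with per-edge confidence drawn from Beta(4, 2) — mass concentrated around
#' 0.6-0.8, mimicking curated physical-interaction confidences — and binary
#' evidence-channel flags for the four accepted physical-binding channels, at
#' least one positive per edge.
#'
#' @param config A [simConfig()].
#' @return An igraph with vertex attribute `name` and edge attributes
#'   `confidence`, `experimental`, `database`, `transferred_experimental`,
#'   `transferred_database`.
#' @export
#' @examples
#' g <- simulateInteractome(simConfig(n_nodes = 100, seed = 7))
#' igraph::ecount(g)
simulateInteractome <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  withSeed(stageSeed(config$seed, "interactome"), {
    n <- config$n_nodes
    if (config$edge_model == "scale-free") {
      m <- max(1L, round(config$mean_degree / 2))
      g <- igraph::sample_pa(n, m = m, directed = FALSE)
    } else {
      repeat {
        deg <- stats::rpois(n, config$mean_degree)
        deg[deg == 0] <- 1L
        if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1L
        if (igraph::is_graphical(deg)) break
      }
      g <- igraph::sample_degseq(deg, method = "configuration")
      g <- igraph::simplify(g)
    }
    comps <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comps$membership ==
                                             which.max(comps$csize)))
    igraph::V(g)$name <- sprintf("P%04d", seq_len(igraph::vcount(g)))
    m_e <- igraph::ecount(g)
    conf <- rbeta(m_e, 4, 2)
    conf[conf <= 0] <- 1e-6
    igraph::E(g)$confidence <- conf
    chans <- list(experimental = 0.6, database = 0.4,
                  transferred_experimental = 0.3, transferred_database = 0.2)
    flagmat <- sapply(chans, function(p) stats::rbinom(m_e, 1L, p))
    flagmat <- matrix(flagmat, nrow = m_e,
                      dimnames = list(NULL, names(chans)))
    none <- rowSums(flagmat) == 0
    flagmat[none, "experimental"] <- 1L
    for (ch in names(chans)) {
      g <- igraph::set_edge_attr(g, ch, value = flagmat[, ch])
    }
    g
  })
}

#' Plant connected dysregulation modules on an interactome
#'
#' Each module is grown by a random-walk/snowball expansion from a random
#' unused seed node, restricted to unused nodes, guaranteeing disjoint,
#' connected induced subgraphs. Because dysregulated functional modules behave
#' like protein complexes — locally dense, unlike the tree-like neighborhoods
#' of preferential-attachment graphs — planting then adds within-module edges
#' (confidence and channel flags drawn like any other edge) until each
#' module's induced subgraph reaches mean internal degree
#' `config$module_degree`; the augmented interactome is returned in
#' `attr(, "interactome")` and is the graph all downstream stages use.
#' Each module carries a condition pattern that fixes the signed true log2
#' effect per condition: `syn_only_up` (+e, 0), `syn_only_down` (-e, 0),
#' `tau_only` (0, +e), `shared_same` (+e, +e), `shared_opposite` (+e, -e).
#'
#' @param interactome Connected igraph from [simulateInteractome()].
#' @param config A [simConfig()].
#' @return A `data.frame` over all interactome nodes with columns `node`,
#'   `module` (NA for unplanted), `pattern` (`"none"` for unplanted),
#'   `effect_syn`, `effect_tau`; the test oracle for recovery. The
#'   module-densified interactome is attached as `attr(, "interactome")`.
#' @export
plantModules <- function(interactome, config) {
  stopifnot(inherits(config, "simConfig"))
  if (igraph::components(interactome)$no != 1L)
    stopConfig("interactome must be connected")
  nodes <- igraph::V(interactome)$name
  withSeed(stageSeed(config$seed, "modules"), {
    used <- character()
    modules <- vector("list", config$n_modules)
    adj <- igraph::as_adj_list(interactome)
    names(adj) <- nodes
    for (i in seq_len(config$n_modules)) {
      size <- config$module_sizes[i]
      ok <- FALSE
      for (try in seq_len(100L)) {
        avail <- setdiff(nodes, used)
        if (length(avail) < size) break
        cur <- sample(avail, 1L)
        while (length(cur) < size) {
          frontier <- unique(unlist(lapply(cur, function(v)
            igraph::V(interactome)$name[as.integer(adj[[v]])])))
          frontier <- setdiff(frontier, c(cur, used))
          if (!length(frontier)) break
          cur <- c(cur, sample(frontier, 1L))
        }
        if (length(cur) == size) { ok <- TRUE; break }
      }
      if (!ok)
        stopConfig("could not place module %d (size %d) after 100 retries",
                   i, size)
      modules[[i]] <- cur
      used <- c(used, cur)
    }
    e <- config$effect_size
    eff <- list(syn_only_up = c(e, 0), syn_only_down = c(-e, 0),
                tau_only = c(0, e), shared_same = c(e, e),
                shared_opposite = c(e, -e))
    gt <- data.frame(node = nodes, module = NA_integer_,
                     pattern = "none", effect_syn = 0, effect_tau = 0,
                     stringsAsFactors = FALSE)
    rownames(gt) <- nodes
    for (i in seq_len(config$n_modules)) {
      pat <- config$module_patterns[i]
      gt[modules[[i]], "module"] <- i
      gt[modules[[i]], "pattern"] <- pat
      gt[modules[[i]], "effect_syn"] <- eff[[pat]][1]
      gt[modules[[i]], "effect_tau"] <- eff[[pat]][2]
    }
    rownames(gt) <- NULL
    # module cohesion: add within-module edges up to the target mean degree
    g2 <- interactome
    for (i in seq_len(config$n_modules)) {
      mn <- modules[[i]]
      sz <- length(mn)
      target <- min(choose(sz, 2), ceiling(config$module_degree * sz / 2))
      have <- igraph::ecount(igraph::induced_subgraph(g2, mn))
      if (have >= target) next
      pairs <- t(combn(mn, 2))
      eid <- igraph::get_edge_ids(g2, as.vector(t(pairs)))
      missing <- pairs[eid == 0, , drop = FALSE]
      add <- missing[sample(nrow(missing), min(target - have, nrow(missing))), ,
                     drop = FALSE]
      if (nrow(add)) {
        n_add <- nrow(add)
        g2 <- igraph::add_edges(
          g2, as.vector(t(add)),
          confidence = { cf <- rbeta(n_add, 4, 2); cf[cf <= 0] <- 1e-6; cf },
          experimental = rep(1L, n_add),
          database = stats::rbinom(n_add, 1L, 0.4),
          transferred_experimental = stats::rbinom(n_add, 1L, 0.3),
          transferred_database = stats::rbinom(n_add, 1L, 0.2))
      }
    }
    attr(gt, "interactome") <- g2
    gt
  })
}

#' Simulate a two-group quantification matrix for one condition
#'
#' Log2 abundance = per-protein baseline (N(10, 2), drawn once per seed and
#' shared across conditions) + planted effect in case samples + N(0, noise_sd).
#' Values are returned on the positive signal-to-noise-like scale (2^log2).
#'
#' @param ground_truth Output of [plantModules()].
#' @param config A [simConfig()].
#' @param condition `"syn"` or `"tau"`.
#' @return A [QuantMatrix-class].
#' @export
simulateQuant <- function(ground_truth, config, condition = c("syn", "tau")) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "simConfig"))
  nodes <- ground_truth$node
  n <- length(nodes)
  baseline <- withSeed(stageSeed(config$seed, "baseline"), rnorm(n, 10, 2))
  eff <- if (condition == "syn") ground_truth$effect_syn else ground_truth$effect_tau
  nc <- config$n_control; nk <- config$n_case
  withSeed(stageSeed(config$seed, paste0("quant_", condition)), {
    noise <- matrix(rnorm(n * (nc + nk), 0, config$noise_sd), n, nc + nk)
    lmat <- baseline + outer(eff, c(rep(0, nc), rep(1, nk))) + noise
    q <- 2^lmat
    dimnames(q) <- list(nodes, c(sprintf("ctrl_%d", seq_len(nc)),
                                 sprintf("case_%d", seq_len(nk))))
    QuantMatrix(q, c(rep("control", nc), rep("case", nk)), condition)
  })
}

#' Simulate matched annotation resources
#'
#' Produces, with structure matched to the planted ground truth: a gene-set
#' collection (one set per planted module plus uniform decoy sets), an ortholog
#' table mapping a fraction of nodes to synthetic human IDs with integer
#' homology scores in 1-15, a GWAS gene-level table with enriched low p-values
#' on a subset of mapped planted genes, and a gene x cell-cluster expression
#' reference with one dominant class per gene.
#'
#' @param ground_truth Output of [plantModules()].
#' @param config A [simConfig()].
#' @return A list with elements `gene_sets` (named list of character vectors),
#'   `orthologs` (data.frame fly_gene/human_gene/score), `gwas` (data.frame
#'   human_gene/p), `celltype` (list `expr` gene x cluster matrix,
#'   `cluster_class` named character), and `gwas_planted` (the human IDs given
#'   enriched p-values, for recovery tests).
#' @export
simulateAnnotations <- function(ground_truth, config) {
  stopifnot(inherits(config, "simConfig"))
  nodes <- ground_truth$node
  withSeed(stageSeed(config$seed, "annotations"), {
    gene_sets <- list()
    for (i in sort(unique(stats::na.omit(ground_truth$module)))) {
      gene_sets[[sprintf("MODULE_%02d", i)]] <-
        ground_truth$node[!is.na(ground_truth$module) & ground_truth$module == i]
    }
    for (j in seq_len(config$n_decoy_sets)) {
      sz <- sample(10:30, 1L)
      gene_sets[[sprintf("DECOY_%02d", j)]] <- sort(sample(nodes, sz))
    }

    mapped <- sort(sample(nodes, round(config$ortholog_fraction * length(nodes))))
    orth <- data.frame(fly_gene = mapped,
                       human_gene = paste0("HUM_", mapped),
                       score = sample(1:15, length(mapped), replace = TRUE),
                       stringsAsFactors = FALSE)
    # a second, lower-scoring ortholog for a few genes (one-to-many mapping)
    extra <- sample(mapped, max(1L, round(0.1 * length(mapped))))
    orth2 <- data.frame(fly_gene = extra,
                        human_gene = paste0("HUM2_", extra),
                        score = sample(1:8, length(extra), replace = TRUE),
                        stringsAsFactors = FALSE)
    orth <- rbind(orth, orth2)
    orth <- orth[order(orth$fly_gene, orth$human_gene), , drop = FALSE]
    rownames(orth) <- NULL

    planted <- ground_truth$node[ground_truth$pattern != "none"]
    planted_mapped <- intersect(planted, mapped)
    n_enr <- min(config$n_gwas_enriched, length(planted_mapped))
    enr_fly <- sample(planted_mapped, n_enr)
    enr_hum <- paste0("HUM_", enr_fly)
    gwas <- data.frame(human_gene = unique(orth$human_gene),
                       p = runif(length(unique(orth$human_gene)), 0.05, 1),
                       stringsAsFactors = FALSE)
    gwas$p[gwas$human_gene %in% enr_hum] <- runif(n_enr, 1e-8, 1e-5)

    clusters <- sprintf("C%02d", 1:6)
    cluster_class <- stats::setNames(
      c("neuronal", "neuronal", "glial", "glial", "unannotated", "unannotated"),
      clusters)
    dom <- sample(clusters, length(nodes), replace = TRUE)
    expr <- matrix(2^rnorm(length(nodes) * length(clusters), 2, 1),
                   length(nodes), length(clusters),
                   dimnames = list(nodes, clusters))
    expr[cbind(seq_along(nodes), match(dom, clusters))] <-
      2^rnorm(length(nodes), 6, 1)

    list(gene_sets = gene_sets, orthologs = orth, gwas = gwas,
         celltype = list(expr = expr, cluster_class = cluster_class),
         gwas_planted = enr_hum)
  })
}
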