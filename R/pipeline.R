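#' Write a ready-to-run fixture directory from the synthetic generator
#'
#' Emits, in the exchange formats the readers consume: per-condition quant and
#' group TSVs, a STRING-style edge TSV, a GMT collection, ortholog / GWAS /
#' cell-type reference TSVs, the planted ground truth as JSON, and a pipeline
#' run-configuration YAML pointing at all of them.
#'
#' @param sim_config A [simConfig()].
#' @param dir Output directory (created if needed).
#' @return Path to the run-configuration YAML, invisibly; the ground truth and
#'   generated objects in `attr(, "objects")`.
#' @export
makeFixtures <- function(sim_config, dir) {
  stopifnot(inherits(sim_config, "simConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g0 <- simulateInteractome(sim_config)
  gt <- plantModules(g0, sim_config)
  g <- attr(gt, "interactome")
  q_syn <- simulateQuant(gt, sim_config, "syn")
  q_tau <- simulateQuant(gt, sim_config, "tau")
  ann <- simulateAnnotations(gt, sim_config)

  p <- function(f) file.path(dir, f)
  writeQuantTSV(q_syn, p("quant_syn.tsv"), p("groups_syn.tsv"))
  writeQuantTSV(q_tau, p("quant_tau.tsv"), p("groups_tau.tsv"))
  writeStringEdges(g, p("edges.tsv"))
  writeGMT(ann$gene_sets, p("gene_sets.gmt"))
  write.table(ann$orthologs, p("orthologs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ann$gwas, p("gwas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ct <- ann$celltype
  write.table(data.frame(gene = rownames(ct$expr), ct$expr,
                         check.names = FALSE),
              p("celltype_expr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(cluster = names(ct$cluster_class),
                         class = unname(ct$cluster_class)),
              p("celltype_class.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(gt, p("ground_truth.json"), digits = NA)

  cfg <- list(
    inputs = list(quant_syn = p("quant_syn.tsv"), groups_syn = p("groups_syn.tsv"),
                  quant_tau = p("quant_tau.tsv"), groups_tau = p("groups_tau.tsv"),
                  edges = p("edges.tsv"), gmt = p("gene_sets.gmt"),
                  orthologs = p("orthologs.tsv"), gwas = p("gwas.tsv"),
                  celltype_expr = p("celltype_expr.tsv"),
                  celltype_class = p("celltype_class.tsv")),
    criterion = list(mode = "bh_fdr", threshold = 0.1),
    enrichment = list(permutations = 200),
    pcsf = list(n_runs = 30, keep_count = 10, n_specificity_rand = 0),
    smoothing = list(alpha = 0.85),
    clustering = list(gamma_res = 4, n_init = 100),
    orthologs = list(min_score = 3),
    gwas = list(p_cutoff = 1e-4),
    seed = sim_config$seed)
  yaml::write_yaml(cfg, p("run_config.yaml"))
  out <- p("run_config.yaml")
  attr(out, "objects") <- list(interactome = g, ground_truth = gt,
                               quant_syn = q_syn, quant_tau = q_tau,
                               annotations = ann)
  invisible(out)
}

#' Read and validate a pipeline run configuration
#'
#' @param path YAML file as written by [makeFixtures()].
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("quant_syn", "groups_syn", "quant_tau", "groups_tau", "edges",
            "gmt", "orthologs", "gwas", "celltype_expr", "celltype_class")
  miss <- setdiff(need, names(cfg$inputs))
  if (length(miss)) stopConfig("run config missing input field(s): %s",
                               paste(miss, collapse = ", "))
  for (f in need)
    if (!file.exists(cfg$inputs[[f]]))
      stopConfig("input '%s' does not exist: %s", f, cfg$inputs[[f]])
  if (is.null(cfg$seed)) stopConfig("run config missing 'seed'")
  if (is.null(cfg$gwas$p_cutoff)) stopConfig("run config missing gwas$p_cutoff")
  cfg
}

.readGroups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$group, df$sample)
}

#' Run the full comparative pipeline
#'
#' Differential expression per condition, overlap statistics, enrichment
#' (over-representation and preranked GSEA), ortholog/GWAS integration,
#' PCSF-based comparative network clustering, and cell-type contingency, with
#' every stage's outputs written to `out_dir` plus a manifest (parameters,
#' derived stage seeds, input checksums). Per-stage seeds are a deterministic
#' hash of the global seed and the stage name, so results are reproducible and
#' stage-local.
#'
#' @param config Configuration list from [readRunConfig()] (or constructed to
#'   the same shape).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results (`de`, `overlap`,
#'   `enrichment`, `gwas_hits`, `network`, `partition`, `celltype`,
#'   `manifest`).
#' @export
runPipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    message(sprintf("[pcsfCompare] stage %s", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  o <- function(f) file.path(out_dir, f)
  wtsv <- function(x, f) write.table(x, o(f), sep = "\t", quote = FALSE,
                                     row.names = FALSE)
  crit <- significanceCriterion(config$criterion$mode %||% "bh_fdr",
                                config$criterion$threshold %||% 0.1)

  qm <- stage("load", list(
    syn = readQuantTSV(config$inputs$quant_syn,
                       .readGroups(config$inputs$groups_syn), "syn"),
    tau = readQuantTSV(config$inputs$quant_tau,
                       .readGroups(config$inputs$groups_tau), "tau")))
  de <- stage("diffexp", lapply(qm, differentialExpression))
  wtsv(de$syn, "de_syn.tsv"); wtsv(de$tau, "de_tau.tsv")

  background <- union(de$syn$protein, de$tau$protein)
  overlap <- stage("overlap", compareOverlap(de$syn, de$tau, background))
  wtsv(overlap, "overlap.tsv")

  gmt <- readGMT(config$inputs$gmt)
  ecfg <- do.call(enrichmentConfig,
                  c(config$enrichment,
                    list(seed = stageSeed(seed, "enrichment"))))
  enr <- stage("enrichment", {
    res <- list()
    for (cond in c("syn", "tau")) {
      sig <- classifySignificant(de[[cond]], crit)
      for (dirn in c("up", "down")) {
        tab <- oraTable(intersect(sig[[dirn]], background), gmt, background)
        res[[paste0("ora_", cond, "_", dirn)]] <- tab
        wtsv(tab, sprintf("ora_%s_%s.tsv", cond, dirn))
      }
      ranked <- stats::setNames(de[[cond]]$log2FC, de[[cond]]$protein)
      gs <- gseaPrerank(ranked, gmt, ecfg)
      res[[paste0("gsea_", cond)]] <- gs
      wtsv(gs, sprintf("gsea_%s.tsv", cond))
    }
    res
  })

  hits <- stage("integration", {
    orth <- readOrthologTSV(config$inputs$orthologs)
    gwas <- readGwasTSV(config$inputs$gwas)
    sig <- classifySignificant(de$syn, crit)
    pairs <- mapOrthologs(c(sig$up, sig$down), orth,
                          min_score = config$orthologs$min_score %||% 1)
    pairs$direction <- ifelse(pairs$fly_gene %in% sig$up, "up", "down")
    intersectGwas(pairs, gwas, p_cutoff = config$gwas$p_cutoff)
  })
  wtsv(hits, "gwas_hits.tsv")

  net <- stage("network", {
    inter <- buildInteractome(readStringEdges(config$inputs$edges))
    pcfg <- do.call(pcsfConfig, c(config$pcsf,
                                  list(seed = stageSeed(seed, "network"))))
    term <- lapply(c(syn = "syn", tau = "tau"), function(cond)
      makeTerminals(de[[cond]], inter, beta = pcfg$beta, condition = cond))
    stable <- lapply(term, function(t) stabilityFilter(inter, t, pcfg))
    specificity <- if (pcfg$n_specificity_rand > 0)
      lapply(term, function(t) specificityNull(inter, t, pcfg)) else NULL
    pooled <- poolNetworks(stable$syn, stable$tau, inter)
    scfg <- do.call(smoothingConfig, as.list(config$smoothing))
    sm <- pagerankSmooth(pooled, lapply(term, `[[`, "weights"), scfg)
    aff <- edgeAffinity(pooled, sm)
    ccfg <- do.call(clusteringConfig,
                    c(config$clustering, list(seed = stageSeed(seed, "louvain"))))
    part <- louvainCluster(pooled, aff, ccfg)
    part <- annotateAndLabel(part, gmt, de$syn, de$tau,
                             igraph::V(inter)$name, ecfg)
    mem <- clusterMembership(part)
    vn <- igraph::V(pooled)$name
    pooled <- igraph::set_vertex_attr(pooled, "cluster",
                                      value = ifelse(vn %in% names(mem),
                                                     mem[vn], NA_integer_))
    pooled <- igraph::set_vertex_attr(pooled, "smoothed_syn", value = sm[vn, "syn"])
    pooled <- igraph::set_vertex_attr(pooled, "smoothed_tau", value = sm[vn, "tau"])
    pooled <- igraph::set_edge_attr(pooled, "affinity", value = aff)
    writeNetworkGraphML(pooled, o("network.graphml"), o("network_nodes.tsv"))
    ctab <- clusterTable(part)
    ctab$significant_at_0.1 <- ctab$fdr < 0.1
    wtsv(ctab, "clusters.tsv")
    if (!is.null(specificity)) {
      wtsv(specificity$syn, "specificity_syn.tsv")
      wtsv(specificity$tau, "specificity_tau.tsv")
    }
    list(interactome = inter, terminals = term, stable = stable,
         specificity = specificity, pooled = pooled, smoothed = sm,
         affinity = aff, partition = part)
  })

  ctres <- stage("celltype", {
    ref <- readCellTypeRef(config$inputs$celltype_expr,
                           config$inputs$celltype_class)
    sig <- classifySignificant(de$syn, crit)
    assign <- assignCellClass(de$syn$protein, ref)
    cont <- regulationContingency(assign, sig$up, sig$down, de$syn$protein)
    wtsv(data.frame(gene = names(assign), class = unname(assign)),
         "celltype_assignments.tsv")
    jsonlite::write_json(
      list(observed = cont$observed, expected = cont$expected,
           statistic = cont$statistic, df = cont$df, p = cont$p,
           low_expected = cont$low_expected),
      o("contingency.json"), digits = NA, auto_unbox = TRUE)
    cont
  })

  manifest <- list(
    package = "pcsfCompare",
    version = as.character(utils::packageVersion("pcsfCompare")),
    stages = c("load", "diffexp", "overlap", "enrichment", "integration",
               "network", "celltype"),
    seed = seed,
    stage_seeds = list(enrichment = stageSeed(seed, "enrichment"),
                       network = stageSeed(seed, "network"),
                       louvain = stageSeed(seed, "louvain")),
    parameters = config[setdiff(names(config), "inputs")],
    input_checksums = as.list(tools::md5sum(unlist(config$inputs))))
  jsonlite::write_json(manifest, o("manifest.json"), digits = NA,
                       auto_unbox = TRUE)

  invisible(list(de = de, overlap = overlap, enrichment = enr,
                 gwas_hits = hits, network = net, partition = net$partition,
                 celltype = ctres, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Module recovery diagnostics against a planted ground truth
#'
#' Compares a cluster partition with the planted modules: the adjusted Rand
#' index over planted nodes that appear in the partition, the fraction of
#' planted nodes recovered, and per-module specificity-label accuracy (each
#' planted module is matched to the cluster holding the majority of its
#' recovered nodes; the cluster's label must equal the module pattern's
#' expected label — syn-only patterns -> "syn", tau_only -> "tau", shared
#' patterns -> "both").
#'
#' @param partition An annotated [ClusterPartition-class].
#' @param ground_truth data.frame from [plantModules()].
#' @return List with `ari`, `recovered_fraction`, `label_accuracy`,
#'   `module_table` (per planted module: nodes recovered, matched cluster,
#'   expected and observed labels).
#' @export
moduleRecovery <- function(partition, ground_truth) {
  mem <- clusterMembership(partition)
  planted <- ground_truth[ground_truth$pattern != "none", , drop = FALSE]
  common <- intersect(planted$node, names(mem))
  rec_frac <- length(common) / nrow(planted)
  ari <- if (length(common) >= 2)
    ariIndex(planted$module[match(common, planted$node)], mem[common])
  else NA_real_
  expLabel <- c(syn_only_up = "syn", syn_only_down = "syn", tau_only = "tau",
                shared_same = "both", shared_opposite = "both")
  ct <- clusterTable(partition)
  rows <- lapply(sort(unique(planted$module)), function(mid) {
    mn <- planted$node[planted$module == mid]
    pat <- planted$pattern[planted$module == mid][1]
    rec <- intersect(mn, names(mem))
    if (!length(rec))
      return(data.frame(module = mid, pattern = pat, size = length(mn),
                        recovered = 0L, cluster = NA_integer_,
                        expected_label = expLabel[[pat]],
                        observed_label = NA_character_, correct = NA,
                        stringsAsFactors = FALSE))
    cl <- as.integer(names(which.max(table(mem[rec]))))
    obs <- ct$specificity[ct$cluster == cl]
    data.frame(module = mid, pattern = pat, size = length(mn),
               recovered = length(rec), cluster = cl,
               expected_label = expLabel[[pat]], observed_label = obs,
               correct = identical(obs, expLabel[[pat]]),
               stringsAsFactors = FALSE)
  })
  mt <- do.call(rbind, rows)
  acc <- mean(mt$correct[!is.na(mt$correct)])
  list(ari = ari, recovered_fraction = rec_frac, label_accuracy = acc,
       module_table = mt)
}
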