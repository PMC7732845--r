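test_that("simConfig validates its fields", {
  expect_s3_class(simConfig(), "simConfig")
  expect_error(simConfig(n_nodes = 5), ">= 10")
  expect_error(simConfig(noise_sd = 0), "> 0")
  expect_error(simConfig(module_sizes = c(2L, rep(10L, 6))), ">= 3")
  expect_error(simConfig(module_patterns = c("bogus", rep("tau_only", 6))),
               "unknown module pattern")
  expect_error(simConfig(n_nodes = 20,
                         module_sizes = c(10L, 10L, 10L, 3L, 3L, 3L, 3L)),
               "exceeds n_nodes")
})

test_that("simulateInteractome: connected, valid confidences and channels, deterministic", {
  cfg <- simConfig(n_nodes = 120, seed = 5)
  g <- simulateInteractome(cfg)
  expect_equal(igraph::components(g)$no, 1L)
  expect_true(all(igraph::E(g)$confidence > 0 & igraph::E(g)$confidence <= 1))
  chans <- cbind(igraph::E(g)$experimental, igraph::E(g)$database,
                 igraph::E(g)$transferred_experimental,
                 igraph::E(g)$transferred_database)
  expect_true(all(rowSums(chans) >= 1))
  g2 <- simulateInteractome(cfg)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  expect_identical(igraph::E(g)$confidence, igraph::E(g2)$confidence)
})

test_that("configuration edge model also yields a connected simple graph", {
  g <- simulateInteractome(simConfig(n_nodes = 100, edge_model = "configuration",
                                     seed = 3))
  expect_equal(igraph::components(g)$no, 1L)
  expect_true(igraph::is_simple(g))
})

test_that("plantModules: disjoint connected modules with the declared patterns", {
  cfg <- simConfig(n_nodes = 150, seed = 2)
  g0 <- simulateInteractome(cfg)
  gt <- plantModules(g0, cfg)
  g <- attr(gt, "interactome")
  expect_setequal(gt$node, igraph::V(g0)$name)
  planted <- gt[!is.na(gt$module), ]
  # sizes and disjointness
  expect_identical(as.integer(table(planted$module)[as.character(1:7)]),
                   as.integer(cfg$module_sizes))
  expect_false(anyDuplicated(planted$node) > 0)
  eff <- list(syn_only_up = c(1, 0), syn_only_down = c(-1, 0),
              tau_only = c(0, 1), shared_same = c(1, 1),
              shared_opposite = c(1, -1))
  for (i in 1:7) {
    mod <- planted[planted$module == i, ]
    # connected induced subgraph on the augmented interactome
    expect_equal(igraph::components(igraph::induced_subgraph(g, mod$node))$no, 1L)
    pat <- unique(mod$pattern)
    expect_length(pat, 1)
    expect_true(all(mod$effect_syn == eff[[pat]][1]))
    expect_true(all(mod$effect_tau == eff[[pat]][2]))
    # densification reached the target internal degree (or the clique bound)
    sz <- nrow(mod)
    target <- min(choose(sz, 2), ceiling(cfg$module_degree * sz / 2))
    expect_gte(igraph::ecount(igraph::induced_subgraph(g, mod$node)), target)
  }
  # unplanted nodes carry no effect
  un <- gt[is.na(gt$module), ]
  expect_true(all(un$effect_syn == 0 & un$effect_tau == 0 & un$pattern == "none"))
  # augmented edges carry valid confidences and channel flags
  expect_true(all(igraph::E(g)$confidence > 0 & igraph::E(g)$confidence <= 1))
})

test_that("simulateQuant plants the effect on the right proteins and is deterministic", {
  cfg <- simConfig(n_nodes = 150, seed = 8, noise_sd = 0.1)
  gt <- plantModules(simulateInteractome(cfg), cfg)
  qs <- simulateQuant(gt, cfg, "syn")
  expect_s4_class(qs, "QuantMatrix")
  expect_equal(dim(quantValues(qs)), c(nrow(gt), cfg$n_control + cfg$n_case))
  lm2 <- log2(quantValues(qs))
  fc <- rowMeans(lm2[, 6:11]) - rowMeans(lm2[, 1:5])
  up <- gt$node[gt$effect_syn == 1]
  none <- gt$node[gt$effect_syn == 0]
  expect_gt(mean(fc[up]), 0.8)
  expect_lt(abs(mean(fc[none])), 0.2)
  # baseline shared across conditions: control means agree up to noise
  qt <- simulateQuant(gt, cfg, "tau")
  cor_base <- cor(rowMeans(log2(quantValues(qs))[, 1:5]),
                  rowMeans(log2(quantValues(qt))[, 1:5]))
  expect_gt(cor_base, 0.99)
  expect_identical(quantValues(simulateQuant(gt, cfg, "syn")), quantValues(qs))
})

test_that("simulateAnnotations matches the planted structure", {
  cfg <- simConfig(n_nodes = 150, seed = 4)
  gt <- plantModules(simulateInteractome(cfg), cfg)
  ann <- simulateAnnotations(gt, cfg)
  # module gene sets equal the planted memberships
  for (i in 1:7)
    expect_setequal(ann$gene_sets[[sprintf("MODULE_%02d", i)]],
                    gt$node[!is.na(gt$module) & gt$module == i])
  expect_length(ann$gene_sets, 7 + cfg$n_decoy_sets)
  expect_true(all(ann$orthologs$score %in% 1:15))
  expect_false(anyDuplicated(ann$orthologs[, c("fly_gene", "human_gene")]) > 0)
  expect_true(all(ann$gwas$p >= 0 & ann$gwas$p <= 1))
  # the planted GWAS genes are recoverable at the 1e-4 convention
  pl <- ann$gwas$p[ann$gwas$human_gene %in% ann$gwas_planted]
  expect_length(pl, cfg$n_gwas_enriched)
  expect_true(all(pl < 1e-4))
  expect_true(all(ann$gwas$p[!ann$gwas$human_gene %in% ann$gwas_planted] >= 0.05))
  expect_setequal(unique(unname(ann$celltype$cluster_class)),
                  c("neuronal", "glial", "unannotated"))
  expect_true(all(ann$celltype$expr >= 0))
})
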