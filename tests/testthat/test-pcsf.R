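test_that("pcsfConfig validates its fields", {
  expect_error(pcsfConfig(beta = 0), "> 0")
  expect_error(pcsfConfig(jitter_sd = -1), ">= 0")
  expect_error(pcsfConfig(keep_count = 300, n_runs = 300), "< n_runs")
})

test_that("edgeCosts: base cost and bounded degree-monotone hub penalty", {
  g <- igraph::make_ring(3)
  igraph::E(g)$confidence <- c(0.9, 1, 0)
  expect_equal(edgeCosts(g, gamma_hub = 0), c(0.6, 0.5, 1.5))
  # ring is degree-regular: penalty is exactly gamma_hub everywhere
  expect_equal(edgeCosts(g, gamma_hub = 4), c(0.6, 0.5, 1.5) + 4)
  # star: the max-degree hub saturates the bound; leaf-leaf edges absent
  st <- igraph::make_star(5, mode = "undirected")
  igraph::E(st)$confidence <- rep(0.5, 4)
  pen <- edgeCosts(st, gamma_hub = 4) - 1
  expect_equal(pen, rep(4 * (4 + 1) / (2 * 4), 4))
  igraph::E(g)$confidence <- c(0.5, 0.5, 1.2)
  expect_error(edgeCosts(g), "\\[0, 1\\]")
})

test_that("pcsfObjective counts trees as nodes minus edges", {
  prizes <- c(a = 2, b = 1, z = 0.5)
  # one edge a-b (cost 0.3) + singleton z: 2 trees
  expect_equal(pcsfObjective(costs = 0.3, prizes, nodes = c("a", "b", "z"),
                             edge_idx = 1L, omega = 1), 0.3 + 2 * 1)
  # exclude z: pay its prize
  expect_equal(pcsfObjective(0.3, prizes, c("a", "b"), 1L, 1), 0.3 + 1 + 0.5)
})

test_that("solvePCSF reproduces hand-solved toy instances", {
  cfg <- pcsfConfig()
  # two prize-2 terminals joined by a cheap edge: take the edge, one tree
  g <- toyGraph(c("a", "b"), 0.9)  # cost 0.6 at gamma_hub = 0
  sol <- solvePCSF(g, c(a = 2, b = 2), cfg, costs = 0.6)
  expect_equal(sol$objective, 0.6 + 1)
  expect_setequal(sol$nodes, c("a", "b"))
  expect_equal(sol$edges, 1L)
  # a single low-prize terminal is cheaper to exclude than to open a tree for
  sol2 <- solvePCSF(g, c(a = 0.1), cfg, costs = 0.6)
  expect_equal(sol2$objective, 0.1)
  expect_length(sol2$nodes, 0)
  # a single high-prize terminal is kept as a singleton at cost omega
  sol3 <- solvePCSF(g, c(a = 1.5), cfg, costs = 5)
  expect_equal(sol3$objective, 1)
  expect_identical(sol3$nodes, "a")
  # an expensive edge between two modest terminals: two singletons win
  sol4 <- solvePCSF(g, c(a = 1.5, b = 1.5), cfg, costs = 5)
  expect_equal(sol4$objective, 2)
  expect_setequal(sol4$nodes, c("a", "b"))
  expect_error(solvePCSF(g, c(zz = 1), cfg), "not in graph")
  expect_error(solvePCSF(g, c(a = -1), cfg), "> 0")
})

test_that("exact solver equals the exhaustive-forest oracle on random instances", {
  set.seed(7)
  cfg <- pcsfConfig()  # omega = 1, exact for <= 15 edges
  for (i in 1:15) {
    inst <- randomPCSFInstance()
    sol <- solvePCSF(inst$graph, inst$prizes, cfg, costs = inst$costs)
    oracle <- oraclePCSF(inst$graph, inst$prizes, inst$costs, omega = 1)
    expect_equal(sol$objective, oracle, tolerance = 1e-9)
    # reported solution is self-consistent with the objective function
    expect_equal(pcsfObjective(inst$costs, inst$prizes, sol$nodes, sol$edges, 1),
                 sol$objective, tolerance = 1e-9)
  }
})

test_that("heuristic solver is feasible and never beats the exact optimum", {
  set.seed(8)
  heur_cfg <- pcsfConfig(exact_edge_limit = 0L)   # force the heuristic path
  exact_cfg <- pcsfConfig()
  for (i in 1:10) {
    inst <- randomPCSFInstance()
    h <- solvePCSF(inst$graph, inst$prizes, heur_cfg, costs = inst$costs)
    e <- solvePCSF(inst$graph, inst$prizes, exact_cfg, costs = inst$costs)
    expect_equal(pcsfObjective(inst$costs, inst$prizes, h$nodes, h$edges, 1),
                 h$objective, tolerance = 1e-9)
    expect_gte(h$objective + 1e-9, e$objective)
  }
})

test_that("stabilityFilter: sigma = 0 keeps exactly the deterministic solution", {
  cfg <- simConfig(n_nodes = 80, seed = 12)
  gt <- plantModules(simulateInteractome(cfg), cfg)
  g <- attr(gt, "interactome")
  de <- suppressMessages(differentialExpression(simulateQuant(gt, cfg, "syn")))
  term <- suppressMessages(makeTerminals(de, g, condition = "syn"))
  pc0 <- pcsfConfig(jitter_sd = 0, n_runs = 5L, keep_count = 2L, seed = 3L)
  sn <- stabilityFilter(g, term, pc0)
  det <- solvePCSF(g, term$prizes, pc0)
  expect_setequal(stableNodes(sn)$node, det$nodes)
  expect_true(all(stableNodes(sn)$frequency == 1))
  # terminal/steiner flags partition the kept set
  nd <- stableNodes(sn)
  expect_identical(nd$steiner, !nd$terminal)
  expect_true(all(nd$node[nd$terminal] %in% names(term$prizes)))
})

test_that("stabilityFilter with jitter is seeded-deterministic and thresholded", {
  cfg <- simConfig(n_nodes = 80, seed = 12)
  gt <- plantModules(simulateInteractome(cfg), cfg)
  g <- attr(gt, "interactome")
  de <- suppressMessages(differentialExpression(simulateQuant(gt, cfg, "syn")))
  term <- suppressMessages(makeTerminals(de, g, condition = "syn"))
  pc <- pcsfConfig(jitter_sd = 0.1, n_runs = 12L, keep_count = 4L, seed = 3L)
  sn1 <- stabilityFilter(g, term, pc)
  sn2 <- stabilityFilter(g, term, pc)
  expect_identical(stableNodes(sn1), stableNodes(sn2))
  expect_true(all(stableNodes(sn1)$frequency > 4 / 12))
})

test_that("specificityNull reports a full node table with valid frequencies", {
  cfg <- simConfig(n_nodes = 80, seed = 12)
  gt <- plantModules(simulateInteractome(cfg), cfg)
  g <- attr(gt, "interactome")
  de <- suppressMessages(differentialExpression(simulateQuant(gt, cfg, "syn")))
  term <- suppressMessages(makeTerminals(de, g, condition = "syn"))
  pc <- pcsfConfig(n_specificity_rand = 10L, seed = 3L)
  nul <- suppressMessages(specificityNull(g, term, pc))
  expect_setequal(nul$node, igraph::V(g)$name)
  expect_true(all(nul$null_freq >= 0 & nul$null_freq <= 1))
  expect_identical(nul$pass, nul$null_freq <= 0.10)
  nul2 <- suppressMessages(specificityNull(g, term, pc))
  expect_identical(nul, nul2)
})
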