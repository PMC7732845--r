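test_that("buildInteractome simplifies with max confidence and keeps the largest CC", {
  tab <- data.frame(from = c("a", "a", "b", "x"),
                    to = c("b", "b", "c", "y"),
                    confidence = c(0.4, 0.9, 0.7, 0.99), stringsAsFactors = FALSE)
  suppressMessages(g <- buildInteractome(tab))
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))  # x-y component dropped
  eid <- igraph::get_edge_ids(g, c("a", "b"))
  expect_equal(igraph::E(g)$confidence[eid], 0.9)        # max kept
  expect_error(buildInteractome(tab[0, ]), "empty")
})

test_that("makeTerminals applies the strict FDR cutoff, clipping, and beta scaling", {
  g <- toyGraph(c("a", "b", "b", "c"), c(0.5, 0.5))
  de <- toyDE(c("a", "b", "c", "d"), log2FC = c(3, -0.5, 0.2, 2),
              q = c(0.01, 0.05, 0.1, 0.01))
  suppressMessages(ts <- makeTerminals(de, g, fdr_cutoff = 0.1, clip = 1, beta = 2,
                                       condition = "syn"))
  # c fails the strict cutoff; d is not in the graph
  expect_setequal(names(ts$prizes), c("a", "b"))
  expect_equal(unname(ts$prizes["a"]), 2 * 1)     # |3| clipped to 1, beta 2
  expect_equal(unname(ts$prizes["b"]), 2 * 0.5)
  expect_equal(unname(ts$weights["a"]), 1)
  expect_identical(ts$condition, "syn")
})

test_that("poolNetworks: union, induced subgraph, origin and Steiner attributes", {
  # path a-b-c-d-e; syn stable {a,b}, tau stable {d,e}: pooling is disconnected,
  # so only the larger component survives -- then with c added they connect.
  g <- toyGraph(c("a", "b", "b", "c", "c", "d", "d", "e"), rep(0.8, 4))
  mkstable <- function(nodes, steiner, cond)
    new("StableNetwork",
        nodes = data.frame(node = nodes, frequency = 1,
                           terminal = !steiner, steiner = steiner),
        condition = cond, n_runs = 10L, keep_count = 3L)
  syn <- mkstable(c("a", "b"), c(FALSE, FALSE), "syn")
  tau <- mkstable(c("b", "c", "d"), c(FALSE, TRUE, FALSE), "tau")
  pooled <- poolNetworks(syn, tau, g)
  expect_setequal(igraph::V(pooled)$name, c("a", "b", "c", "d"))
  vn <- igraph::V(pooled)$name
  origin <- stats::setNames(igraph::V(pooled)$origin, vn)
  expect_identical(unname(origin[c("a", "b", "c", "d")]),
                   c("syn", "both", "tau", "tau"))
  st_tau <- stats::setNames(igraph::V(pooled)$steiner_tau, vn)
  expect_true(st_tau[["c"]]); expect_false(st_tau[["b"]])
  # disjoint stable sets connected through an interactome edge stay together
  syn2 <- mkstable("c", FALSE, "syn")
  tau2 <- mkstable("d", FALSE, "tau")
  pooled2 <- poolNetworks(syn2, tau2, g)
  expect_setequal(igraph::V(pooled2)$name, c("c", "d"))
})

test_that("pagerankSmooth: stochastic vectors, symmetry, and the 2-node closed form", {
  # regular graph + uniform personalization -> uniform scores
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- letters[1:6]
  igraph::E(ring)$confidence <- 1
  sm <- pagerankSmooth(ring, list(u = stats::setNames(rep(1, 6), letters[1:6])))
  expect_equal(unname(sm[, "u"]), rep(1 / 6, 6), tolerance = 1e-9)
  # 2-node closed form: x = (1 - a) v + a P^T x with P the walk matrix
  g2 <- toyGraph(c("a", "b"), 1)
  sm2 <- pagerankSmooth(g2, list(syn = c(a = 1)), smoothingConfig(0.85))
  A <- diag(2) - 0.85 * matrix(c(0, 1, 1, 0), 2, 2)
  x <- solve(A, 0.15 * c(1, 0))
  expect_equal(unname(sm2[c("a", "b"), "syn"]), x, tolerance = 1e-9)
  expect_equal(sum(sm2[, "syn"]), 1, tolerance = 1e-9)
  # zero prize mass falls back to uniform with a message
  expect_message(sm3 <- pagerankSmooth(g2, list(tau = c(zz = 1))), "uniform")
  expect_equal(unname(sm3[, "tau"]), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("edgeAffinity: cosine values on hand-checkable vectors", {
  g <- toyGraph(c("a", "b", "b", "c", "c", "a"), rep(1, 3))
  sm <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1))
  colnames(sm) <- c("syn", "tau")
  aff <- edgeAffinity(g, sm)
  el <- igraph::ends(g, igraph::E(g))
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  aff <- stats::setNames(aff, key)
  expect_equal(unname(aff["a b"]), 0)                       # orthogonal
  expect_equal(unname(aff["b c"]), 1 / sqrt(2), tolerance = 1e-5)
  expect_equal(unname(aff["a c"]), 1 / sqrt(2), tolerance = 1e-5)
  # zero-norm endpoint -> affinity 0 with a message
  sm0 <- rbind(a = c(0, 0), b = c(1, 0), c = c(1, 1)); colnames(sm0) <- c("syn", "tau")
  expect_message(aff0 <- edgeAffinity(g, sm0), "zero-norm")
  expect_equal(unname(aff0[igraph::get_edge_ids(g, c("a", "b"))]), 0)
})

test_that("louvainCluster recovers two planted cliques and discards singletons", {
  # two 5-cliques joined by one weak edge
  g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("n", 1:10)
  aff <- c(rep(1, 20), 1e-4)
  part <- louvainCluster(g, aff, clusteringConfig(gamma_res = 1, n_init = 20, seed = 2))
  mem <- clusterMembership(part)
  expect_equal(length(unique(mem)), 2)
  expect_equal(length(unique(mem[paste0("n", 1:5)])), 1)
  expect_equal(length(unique(mem[paste0("n", 6:10)])), 1)
  # determinism across calls
  part2 <- louvainCluster(g, aff, clusteringConfig(gamma_res = 1, n_init = 20, seed = 2))
  expect_identical(clusterMembership(part2), mem)
  expect_error(louvainCluster(g, rep(0, 21), clusteringConfig()), "no positive-weight")
  expect_error(louvainCluster(g, 1, clusteringConfig()), "one affinity per edge")
})

test_that("annotateAndLabel picks the lowest-p term and applies the 30% rule", {
  # pooled partition: cluster 1 = m1..m5 (planted term), cluster 2 = x1..x5
  mem <- stats::setNames(c(rep(1L, 5), rep(2L, 5)),
                         c(paste0("m", 1:5), paste0("x", 1:5)))
  part <- new("ClusterPartition", membership = mem,
              clusters = data.frame(cluster = 1:2, size = c(5L, 5L)),
              modularity = 0.3)
  background <- c(names(mem), paste0("bg", 1:30))
  gene_sets <- list(GOOD = paste0("m", 1:5),
                    WEAK = c(paste0("m", 1:2), paste0("bg", 1:6)),
                    TOOBIG = background)
  # syn dysregulation: all of cluster 1 (fraction 1 > 0.3); tau: 1/5 (not > 0.3)
  de_syn <- toyDE(background, rep(1, length(background)),
                  q = ifelse(background %in% paste0("m", 1:5), 0.01, 0.5))
  de_tau <- toyDE(background, rep(1, length(background)),
                  q = ifelse(background == "m1", 0.01, 0.5))
  ann <- suppressMessages(annotateAndLabel(part, gene_sets, de_syn, de_tau,
                                           background))
  ct <- clusterTable(ann)
  expect_identical(ct$term[ct$cluster == 1], "GOOD")
  expect_identical(ct$specificity[ct$cluster == 1], "syn")
  expect_identical(ct$specificity[ct$cluster == 2], "neither")
  expect_equal(ct$frac_syn[ct$cluster == 1], 1)
  expect_equal(ct$frac_tau[ct$cluster == 1], 0.2)
  # the full test table carries BH across all cluster x term tests
  tests <- attr(ct, "tests")
  expect_equal(tests$fdr, p.adjust(tests$p, "BH"))
  # exactly 30% must NOT trigger a label (strict rule): 3 of 10 nodes
  mem2 <- stats::setNames(rep(1L, 10), paste0("y", 1:10))
  part2 <- new("ClusterPartition", membership = mem2,
               clusters = data.frame(cluster = 1L, size = 10L), modularity = 0)
  bg2 <- names(mem2)
  de3 <- toyDE(bg2, rep(1, 10), q = c(rep(0.01, 3), rep(0.5, 7)))
  de0 <- toyDE(bg2, rep(1, 10), q = rep(0.5, 10))
  ann2 <- suppressMessages(annotateAndLabel(part2, list(), de3, de0, bg2))
  expect_identical(clusterTable(ann2)$specificity, "neither")
  expect_identical(clusterTable(ann2)$term, "unannotated")
})

test_that("compareOverlap counts per-direction overlaps with Fisher p", {
  bg <- paste0("p", 1:50)
  de_syn <- toyDE(bg, log2FC = rep(c(1, -1), 25),
                  q = rep(0.5, 50), p = c(rep(0.01, 10), rep(0.5, 40)))
  de_tau <- toyDE(bg, log2FC = rep(c(1, -1), 25),
                  q = rep(0.5, 50), p = c(rep(0.01, 6), rep(0.5, 44)))
  ov <- compareOverlap(de_syn, de_tau, bg)
  up <- ov[ov$direction == "up", ]
  expect_equal(up$n_syn, 5); expect_equal(up$n_tau, 3); expect_equal(up$overlap, 3)
  tab <- matrix(c(3, 5 - 3, 3 - 3, 50 - 5 - 3 + 3), 2, 2)
  expect_equal(up$p, fisher.test(tab)$p.value)
  # identical sets -> full overlap; disjoint background error
  ov2 <- compareOverlap(de_syn, de_syn, bg)
  expect_equal(ov2$overlap, ov2$n_syn)
  expect_error(compareOverlap(de_syn, de_tau, character()), "empty background")
})
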