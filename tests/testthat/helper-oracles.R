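# Independent oracle implementations used by the unit and acceptance tests.
# These are deliberately naive re-derivations (brute force / closed form),
# sharing no code with the package internals they check.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} min(1, m p_(j) / j).
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- min(1, running)
  }
  q
}

# Hypergeometric upper tail by summing the pmf.
oracleHyperUpper <- function(r, R, n, N) {
  ks <- r:min(n, R)
  sum(choose(R, ks) * choose(N - R, n - ks)) / choose(N, n)
}

# GO-Elite-style z with finite-population correction.
oracleZ <- function(r, R, n, N) {
  f <- R / N
  (r - n * f) / sqrt(n * f * (1 - f) * (1 - (n - 1) / (N - 1)))
}

# Pearson chi-square statistic and upper-tail p from an observed table.
oracleChisq <- function(obs) {
  E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - E)^2 / E)
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# Naive average-linkage agglomeration on a distance matrix, returning the
# cophenetic distance matrix (the height at which each pair is first merged).
oracleAverageLinkCophenetic <- function(D) {
  n <- nrow(D)
  groups <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(groups))
  gdist <- function(a, b) mean(D[groups[[a]], groups[[b]], drop = FALSE])
  while (sum(active) > 1) {
    idx <- which(active)
    best <- NULL
    for (ai in seq_along(idx)) for (bi in seq_along(idx)) {
      if (bi <= ai) next
      d <- gdist(idx[ai], idx[bi])
      if (is.null(best) || d < best$d) best <- list(a = idx[ai], b = idx[bi], d = d)
    }
    for (u in groups[[best$a]]) for (v in groups[[best$b]]) {
      coph[u, v] <- best$d; coph[v, u] <- best$d
    }
    groups[[length(groups) + 1L]] <- c(groups[[best$a]], groups[[best$b]])
    active[c(best$a, best$b)] <- FALSE
    active[length(groups)] <- TRUE
  }
  coph
}

# Exhaustive prize-collecting Steiner forest: enumerate every subset of edges,
# keep the acyclic ones, and complete each with the forced-optimal choice for
# uncovered terminals (pay min(prize, omega): exclude it or open a singleton
# tree). Returns the minimal objective.
oraclePCSF <- function(graph, prizes, costs, omega) {
  m <- igraph::ecount(graph)
  el <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  vnames <- igraph::V(graph)$name
  term <- names(prizes)
  best <- sum(pmin(prizes, omega))  # empty forest + optimal singletons
  for (mask in seq_len(2^m) - 1L) {
    if (mask == 0L) next
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    # forest check via union-find over vertex names
    parent <- stats::setNames(vnames, vnames)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    acyclic <- TRUE
    for (e in sel) {
      ra <- find(el[e, 1]); rb <- find(el[e, 2])
      if (ra == rb) { acyclic <- FALSE; break }
      parent[[ra]] <- rb
    }
    if (!acyclic) next
    covered <- unique(as.vector(el[sel, , drop = FALSE]))
    n_trees <- length(covered) - length(sel)
    rest <- setdiff(term, covered)
    obj <- sum(costs[sel]) + omega * n_trees + sum(pmin(prizes[rest], omega))
    if (obj < best) best <- obj
  }
  best
}

# Random small PCSF instance (connected-ish graph, random prizes and costs).
randomPCSFInstance <- function(max_nodes = 8, max_edges = 12) {
  n <- sample(3:max_nodes, 1)
  pairs <- t(combn(n, 2))
  m <- sample(seq_len(min(max_edges, nrow(pairs))), 1)
  sel <- pairs[sample(nrow(pairs), m), , drop = FALSE]
  g <- igraph::graph_from_edgelist(matrix(letters[sel], ncol = 2), directed = FALSE)
  costs <- round(runif(igraph::ecount(g), 0.1, 2), 3)
  vn <- igraph::V(g)$name
  k <- sample(seq_len(length(vn)), 1)
  prizes <- stats::setNames(round(runif(k, 0.05, 3), 3), sample(vn, k))
  list(graph = g, costs = costs, prizes = prizes)
}

# Exhaustive GSEA null for a ranked list and set size k: the weighted-KS
# enrichment score of every same-size subset, recomputed from the definition.
oracleGseaES <- function(scores_sorted, hit_idx) {
  n <- length(scores_sorted)
  hit <- logical(n); hit[hit_idx] <- TRUE
  w <- abs(scores_sorted)
  sh <- sum(w[hit])
  step <- ifelse(hit, if (sh > 0) w / sh else 1 / sum(hit), -1 / (n - sum(hit)))
  run <- cumsum(step)
  run[which.max(abs(run))]
}
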