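#' PCSF configuration
#'
#' Parameters of the prize-collecting Steiner forest stage: prize scaling
#' beta = 2 and hub penalty gamma = 4 by default, edge costs 1.5 minus the
#' interaction confidence, Gaussian edge-cost jitter sigma = 0.1 over 300
#' runs keeping nodes detected in more than 100, and a degree-preserving
#' terminal-randomization specificity null at a 10\% cutoff.
#'
#' @param beta Prize scaling factor (> 0).
#' @param gamma_hub Hub penalty strength (>= 0); an additive degree-monotone
#'   cost term bounded by `gamma_hub` (see [edgeCosts()]).
#' @param omega Tree-opening cost (virtual root edge cost); the rooted-PCST
#'   reduction constant, configurable.
#' @param jitter_sd Gaussian jitter SD on edge costs (>= 0).
#' @param n_runs Number of jittered solves.
#' @param keep_count Strict detection-count threshold (< n_runs).
#' @param n_specificity_rand Number of degree-preserving terminal
#'   randomizations.
#' @param specificity_cutoff Null appearance frequency above which a node is
#'   flagged (strict).
#' @param exact_edge_limit Instances with at most this many edges are solved
#'   exactly by branch-and-bound enumeration; larger instances use the
#'   shortest-path heuristic with strong pruning.
#' @param seed Integer seed for jitter and randomization.
#' @return List of class `"pcsfConfig"`.
#' @export
pcsfConfig <- function(beta = 2, gamma_hub = 4, omega = 1.0, jitter_sd = 0.1,
                       n_runs = 300L, keep_count = 100L,
                       n_specificity_rand = 100L, specificity_cutoff = 0.10,
                       exact_edge_limit = 15L, seed = 1L) {
  if (beta <= 0) stopConfig("beta must be > 0")
  if (gamma_hub < 0) stopConfig("gamma_hub must be >= 0")
  if (jitter_sd < 0) stopConfig("jitter_sd must be >= 0")
  if (keep_count >= n_runs) stopConfig("keep_count must be < n_runs")
  structure(list(beta = beta, gamma_hub = gamma_hub, omega = omega,
                 jitter_sd = jitter_sd, n_runs = as.integer(n_runs),
                 keep_count = as.integer(keep_count),
                 n_specificity_rand = as.integer(n_specificity_rand),
                 specificity_cutoff = specificity_cutoff,
                 exact_edge_limit = as.integer(exact_edge_limit),
                 seed = as.integer(seed)),
            class = "pcsfConfig")
}

#' Hub-penalized PCSF edge costs
#'
#' Base cost is 1.5 minus the interaction confidence. The hub penalty is an
#' additive, degree-monotone term bounded by `gamma_hub`:
#' cost'(u,v) = (1.5 - confidence) + gamma_hub * (deg(u) + deg(v)) /
#' (2 * max_degree). This is a stated convention of the package (pinned by
#' tests), not a universal definition.
#'
#' @param graph igraph with edge attribute `confidence` in [0, 1].
#' @param gamma_hub Penalty strength.
#' @return Numeric vector of per-edge costs (order of `igraph::E(graph)`).
#' @export
#' @examples
#' g <- igraph::make_ring(3)
#' igraph::E(g)$confidence <- c(0.9, 1, 0)
#' edgeCosts(g, gamma_hub = 0)  # 0.6 0.5 1.5
edgeCosts <- function(graph, gamma_hub = 4) {
  conf <- igraph::E(graph)$confidence
  if (is.null(conf)) stopConfig("graph has no 'confidence' edge attribute")
  if (any(conf < 0 | conf > 1)) stopConfig("confidence outside [0, 1]")
  base <- 1.5 - conf
  if (gamma_hub == 0 || igraph::ecount(graph) == 0) return(base)
  deg <- igraph::degree(graph)
  el <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  base + gamma_hub * (deg[el[, 1]] + deg[el[, 2]]) / (2 * max(deg))
}

#' PCSF objective of a candidate forest
#'
#' Sum of chosen edge costs, plus `omega` per tree (a tree is a connected
#' component of the forest, including singleton nodes), plus the prizes of
#' terminals excluded from the forest. For a forest, the number of trees is
#' `length(nodes) - length(edge_idx)`.
#'
#' @param costs Per-edge cost vector (order of `igraph::E(graph)`).
#' @param prizes Named terminal prize vector.
#' @param nodes Character vector of forest nodes (covering all chosen edges).
#' @param edge_idx Integer indices of chosen edges.
#' @param omega Tree-opening cost.
#' @return The objective value.
#' @export
pcsfObjective <- function(costs, prizes, nodes, edge_idx, omega) {
  n_trees <- length(nodes) - length(edge_idx)
  sum(costs[edge_idx]) + omega * n_trees +
    sum(prizes[setdiff(names(prizes), nodes)])
}

# exact branch-and-bound over acyclic edge subsets; optimal singleton
# augmentation at each leaf. Deterministic: fixed edge order, first best kept.
.pcsfExact <- function(graph, prizes, costs, omega) {
  m <- igraph::ecount(graph)
  el <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  term <- names(prizes)
  # singleton value of a terminal: include iff prize > omega (strictly)
  singleGain <- pmin(prizes, omega)  # cost paid for terminal when not edge-covered
  best <- list(obj = sum(singleGain), nodes = term[prizes > omega],
               edges = integer())
  # parent maps for union-find over node names
  nodes_all <- igraph::V(graph)$name
  find <- function(par, x) { while (par[[x]] != x) x <- par[[x]]; x }
  rec <- function(i, par, chosen, edge_cost) {
    if (i > m) {
      covered <- unique(as.vector(el[chosen, , drop = FALSE]))
      ncomp_edges <- length(covered) - length(chosen)
      rest <- setdiff(term, covered)
      obj <- edge_cost + omega * ncomp_edges + sum(pmin(prizes[rest], omega))
      nodes <- c(covered, rest[prizes[rest] > omega])
      if (obj < best$obj - 1e-12) {
        best <<- list(obj = obj, nodes = nodes, edges = chosen)
      }
      return(invisible(NULL))
    }
    # bound: edge costs already paid cannot be recovered; prune when even
    # paying nothing further cannot beat the incumbent
    if (edge_cost >= best$obj - 1e-12) return(invisible(NULL))
    # branch 1: include edge i if it does not close a cycle
    a <- el[i, 1]; b <- el[i, 2]
    ra <- find(par, a); rb <- find(par, b)
    if (ra != rb) {
      par2 <- par; par2[[ra]] <- rb
      rec(i + 1L, par2, c(chosen, i), edge_cost + costs[i])
    }
    # branch 2: exclude edge i
    rec(i + 1L, par, chosen, edge_cost)
    invisible(NULL)
  }
  par0 <- as.list(stats::setNames(nodes_all, nodes_all))
  rec(1L, par0, integer(), 0)
  best
}

# strong pruning of one tree (igraph, subset of `graph`) rooted at `root`:
# returns kept vertex names and the net value at the root.
.strongPrune <- function(tree, root, prizes, cost_attr = "cost") {
  vs <- igraph::V(tree)$name
  pr <- stats::setNames(rep(0, length(vs)), vs)
  pr[intersect(vs, names(prizes))] <- prizes[intersect(vs, names(prizes))]
  if (length(vs) == 1L) return(list(keep = vs, value = unname(pr[vs])))
  # BFS order from root; process in reverse (post-order over the tree)
  bf <- igraph::bfs(tree, root = root, father = TRUE)
  ordv <- as.integer(bf$order)
  father <- as.integer(bf$father)
  nv <- pr[vs]
  kept_children <- vector("list", length(vs))
  for (vi in rev(ordv)) {
    fa <- father[vi]
    if (is.na(fa)) next
    eid <- igraph::get_edge_ids(tree, c(fa, vi))
    ec <- igraph::edge_attr(tree, cost_attr, eid)
    gain <- nv[vs[vi]] - ec
    if (gain > 1e-12) {
      nv[vs[fa]] <- nv[vs[fa]] + gain
      kept_children[[fa]] <- c(kept_children[[fa]], vi)
    }
  }
  # collect kept vertices from root down
  keep <- integer()
  stack <- as.integer(igraph::V(tree)[root])
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    keep <- c(keep, v)
    stack <- c(stack, kept_children[[v]])
  }
  list(keep = vs[keep], value = unname(nv[vs[as.integer(igraph::V(tree)[root])]]))
}

.pcsfHeuristic <- function(graph, prizes, costs, omega) {
  term <- names(prizes)[prizes > 0]
  empty <- list(obj = sum(prizes), nodes = character(), edges = integer())
  if (!length(term)) return(empty)
  g <- igraph::set_edge_attr(graph, "cost", value = costs)
  # terminal metric closure
  D <- igraph::distances(g, v = term, to = term, weights = costs)
  k <- length(term)
  # MST over terminals + virtual root (root edges cost omega)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  mel <- rbind(cbind(idx[, 1], idx[, 2]),
               cbind(rep(k + 1L, k), seq_len(k)))
  mw <- c(D[idx], rep(omega, k))
  finite <- is.finite(mw)
  mg <- igraph::graph_from_edgelist(mel[finite, , drop = FALSE], directed = FALSE)
  igraph::E(mg)$weight <- mw[finite]
  mt <- igraph::mst(mg, weights = igraph::E(mg)$weight)
  # expand non-root MST edges into shortest paths in the interactome
  mtel <- igraph::as_edgelist(mt, names = FALSE)
  eids <- integer()
  for (r in seq_len(nrow(mtel))) {
    a <- mtel[r, 1]; b <- mtel[r, 2]
    if (a > k || b > k) next  # root edge
    sp <- igraph::shortest_paths(g, from = term[a], to = term[b],
                                 weights = costs, output = "epath")
    eids <- union(eids, as.integer(sp$epath[[1]]))
  }
  # candidate subgraph: expanded paths plus all terminals; per-component MST
  sub <- igraph::subgraph_from_edges(g, igraph::E(g)[eids],
                                     delete.vertices = TRUE)
  lone <- setdiff(term, igraph::V(sub)$name)
  sub <- igraph::add_vertices(sub, length(lone), name = lone)
  sub <- igraph::mst(sub, weights = igraph::E(sub)$cost)
  # strong pruning per component against the root-opening cost omega
  comp <- igraph::components(sub)
  nodes <- character(); kept_pairs <- NULL
  for (ci in seq_len(comp$no)) {
    cvs <- igraph::V(sub)$name[comp$membership == ci]
    tvs <- intersect(cvs, term)
    if (!length(tvs)) next
    tr <- igraph::induced_subgraph(sub, cvs)
    root <- tvs[which.max(prizes[tvs])]
    prn <- .strongPrune(tr, root, prizes)
    if (prn$value > omega + 1e-12) {
      keep_tr <- igraph::induced_subgraph(tr, prn$keep)
      nodes <- c(nodes, prn$keep)
      eel <- igraph::as_edgelist(keep_tr)
      if (nrow(eel)) kept_pairs <- rbind(kept_pairs, eel)
    }
  }
  # singleton augmentation for terminals still excluded
  nodes <- c(nodes, setdiff(term[prizes[term] > omega], nodes))
  edge_idx <- if (is.null(kept_pairs)) integer() else
    as.integer(igraph::get_edge_ids(g, as.vector(t(kept_pairs))))
  sol <- list(obj = pcsfObjective(costs, prizes, nodes, edge_idx, omega),
              nodes = nodes, edges = edge_idx)
  if (empty$obj < sol$obj) empty else sol
}

#' Solve a prize-collecting Steiner forest instance
#'
#' Minimizes sum of excluded terminal prizes + sum of chosen edge costs +
#' `omega` per tree. Instances with at most `config$exact_edge_limit` edges
#' are solved exactly by branch-and-bound enumeration of acyclic edge subsets
#' (with optimal singleton augmentation); larger instances use a shortest-path
#' Steiner heuristic (terminal metric closure, MST against a virtual root at
#' cost `omega`, path expansion, re-MST, strong pruning).
#'
#' @param graph igraph interactome; edge costs are taken from `costs` if
#'   given, else computed by [edgeCosts()] with `config$gamma_hub`.
#' @param prizes Named numeric vector of terminal prizes (> 0), names being
#'   graph nodes.
#' @param config A [pcsfConfig()].
#' @param costs Optional per-edge cost vector overriding [edgeCosts()].
#' @return List with `nodes` (character), `edges` (integer edge indices into
#'   `igraph::E(graph)`), `objective`.
#' @export
solvePCSF <- function(graph, prizes, config = pcsfConfig(), costs = NULL) {
  stopifnot(inherits(config, "pcsfConfig"))
  if (length(prizes)) {
    bad <- setdiff(names(prizes), igraph::V(graph)$name)
    if (length(bad)) stopConfig("terminal(s) not in graph: %s",
                                paste(head(bad, 3), collapse = ", "))
    if (any(prizes <= 0)) stopConfig("prizes must be > 0")
  }
  if (is.null(costs)) costs <- edgeCosts(graph, config$gamma_hub)
  if (length(costs) != igraph::ecount(graph))
    stopConfig("need one cost per edge")
  sol <- if (igraph::ecount(graph) <= config$exact_edge_limit)
    .pcsfExact(graph, prizes, costs, config$omega)
  else
    .pcsfHeuristic(graph, prizes, costs, config$omega)
  list(nodes = sort(sol$nodes), edges = sort(sol$edges), objective = sol$obj)
}

#' Jitter-stability filtering of PCSF solutions
#'
#' Solves the PCSF `config$n_runs` times with independent Gaussian
#' (0, `config$jitter_sd`) perturbations added to the edge costs (floored at
#' 1e-6 to stay positive) and keeps the nodes detected in strictly more than
#' `config$keep_count` solutions. With `jitter_sd = 0` all runs coincide and
#' the kept set equals the single deterministic solution.
#'
#' @param graph igraph interactome.
#' @param terminals A terminal set from [makeTerminals()].
#' @param config A [pcsfConfig()].
#' @return A [StableNetwork-class].
#' @export
stabilityFilter <- function(graph, terminals, config = pcsfConfig()) {
  stopifnot(inherits(terminals, "terminalSet"))
  prizes <- terminals$prizes
  base <- edgeCosts(graph, config$gamma_hub)
  m <- igraph::ecount(graph)
  counts <- stats::setNames(numeric(igraph::vcount(graph)),
                            igraph::V(graph)$name)
  withSeed(stageSeed(config$seed, paste0("stability_", terminals$condition)), {
    for (r in seq_len(config$n_runs)) {
      cst <- pmax(base + rnorm(m, 0, config$jitter_sd), 1e-6)
      sol <- solvePCSF(graph, prizes, config, costs = cst)
      counts[sol$nodes] <- counts[sol$nodes] + 1
    }
  })
  freq <- counts / config$n_runs
  kept <- names(freq)[counts > config$keep_count]
  nd <- data.frame(node = kept, frequency = unname(freq[kept]),
                   terminal = kept %in% names(prizes),
                   stringsAsFactors = FALSE)
  nd$steiner <- !nd$terminal
  nd <- nd[order(nd$node), , drop = FALSE]
  rownames(nd) <- NULL
  new("StableNetwork", nodes = nd, condition = terminals$condition,
      n_runs = config$n_runs, keep_count = config$keep_count)
}

# degree-decile bins over the graph's degree distribution; returns an integer
# bin id per node.
.degreeBins <- function(graph, n_bins = 10L) {
  deg <- igraph::degree(graph)
  br <- unique(stats::quantile(deg, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(stats::setNames(rep(1L, length(deg)), names(deg)))
  bins <- cut(deg, breaks = br, include.lowest = TRUE, labels = FALSE)
  stats::setNames(as.integer(bins), igraph::V(graph)$name)
}

#' Degree-preserving terminal-randomization specificity null
#'
#' Draws `config$n_specificity_rand` random terminal sets with the true set's
#' size and degree profile (sampled within degree-decile bins of the
#' interactome degree distribution; a bin with too few candidates is widened
#' to its neighbors with a message), permutes the true prizes onto them,
#' re-solves the PCSF once per randomization, and reports each node's
#' appearance frequency. Nodes above `config$specificity_cutoff` (strictly)
#' fail.
#'
#' @inheritParams stabilityFilter
#' @return data.frame over all graph nodes: `node`, `null_freq`, `pass`.
#' @export
specificityNull <- function(graph, terminals, config = pcsfConfig()) {
  stopifnot(inherits(terminals, "terminalSet"))
  prizes <- terminals$prizes
  bins <- .degreeBins(graph)
  nodes_all <- igraph::V(graph)$name
  true_bins <- bins[names(prizes)]
  need <- table(true_bins)
  costs <- edgeCosts(graph, config$gamma_hub)
  counts <- stats::setNames(numeric(length(nodes_all)), nodes_all)
  withSeed(stageSeed(config$seed, paste0("specificity_", terminals$condition)), {
    for (r in seq_len(config$n_specificity_rand)) {
      picked <- character()
      for (b in as.integer(names(need))) {
        cand <- nodes_all[bins == b]
        width <- 0L
        while (length(setdiff(cand, picked)) < need[[as.character(b)]]) {
          width <- width + 1L
          message(sprintf("[pcsfCompare] specificityNull: widening degree bin %d by %d",
                          b, width))
          cand <- nodes_all[abs(bins - b) <= width]
        }
        picked <- c(picked, sample(setdiff(cand, picked),
                                   need[[as.character(b)]]))
      }
      rp <- stats::setNames(sample(unname(prizes)), picked)
      sol <- solvePCSF(graph, rp, config, costs = costs)
      counts[sol$nodes] <- counts[sol$nodes] + 1
    }
  })
  nf <- counts / config$n_specificity_rand
  data.frame(node = nodes_all, null_freq = unname(nf),
             pass = unname(nf) <= config$specificity_cutoff,
             stringsAsFactors = FALSE)
}
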