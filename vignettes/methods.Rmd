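---
title: "pcsfCompare: models, parameters, and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pcsfCompare: models, parameters, and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented by pcsfCompare,
the conventions behind every fixed parameter, the design of the synthetic
benchmark generator (including what it deliberately does and does not mimic),
and the numerical choices that make results exactly reproducible.

## 1. The analysis model

The pipeline compares two disease conditions (`syn`, `tau`) profiled as
protein × sample abundance matrices against one shared confidence-weighted
interactome.

### 1.1 Differential expression

Abundances are log2-transformed; per protein we test
$H_0: \mu_{case} = \mu_{ctrl}$ with a two-sided two-sample t-test, **Welch**
by default. Rationale: with 5 vs 6 samples, pooling variances buys little
power but is biased under heteroscedasticity; Welch is the safer default, and
`var.equal = TRUE` restores the Student variant. The log2 fold change is
$\Delta = \bar x_{case} - \bar x_{ctrl}$. Multiplicity is controlled by
Benjamini–Hochberg (BH) step-up across all tested proteins; all thresholds in
the package are **strict** inequalities (`q < 0.1` etc.), a single pinned
convention so that boundary cases are never ambiguous. Degenerate rows
(zero variance in both groups) are handled explicitly: equal means give
$t = 0, p = 1$; unequal means give $t = \pm\infty, p = 0$.

### 1.2 Prizes, costs, and the PCSF objective

Terminals are proteins at BH $q < 0.1$ present in the interactome, with prize
$p(v) = \beta\,\min(|\Delta(v)|, 1)$, $\beta = 2$. Clipping at 1 caps the
influence of extreme fold changes; $\beta$ balances prizes against edge
costs. Edge costs are

$$\mathrm{cost}(u,v) = (1.5 - c_{uv}) + \gamma_{hub}\,
\frac{\deg u + \deg v}{2\,\max_w \deg w}, \qquad \gamma_{hub} = 4 ,$$

with $c_{uv} \in [0,1]$ the interaction confidence. The base term keeps even
perfect-confidence edges strictly positive (cost 0.5), so solutions cannot
grow for free; the hub term is an additive, degree-monotone penalty bounded
by $\gamma_{hub}$ — the exact functional form is a package convention pinned
by tests, chosen to make the penalty scale-free across graphs.

The prize-collecting Steiner **forest** minimizes

$$\sum_{v \in T \setminus V_F} p(v) \;+\; \sum_{e \in E_F} \mathrm{cost}(e)
\;+\; \omega\,\tau(F),$$

where $\tau(F)$ is the number of trees (connected components, singletons
included) and $\omega = 1$ is the tree-opening cost from the standard rooted
reduction (a virtual root connected to every terminal by an $\omega$-cost
edge). Consequences used by tests: a lone terminal is worth keeping as a
singleton iff $p(v) > \omega$ (strictly), and for any forest
$\tau(F) = |V_F| - |E_F|$.

**Solver.** Instances with at most 15 edges are solved *exactly* by
branch-and-bound over acyclic edge subsets, each leaf completed by the forced
optimum for uncovered terminals ($\min(p(v), \omega)$ each). Larger instances
use a classical Steiner heuristic: terminal metric closure → MST including
the virtual root → expansion of MST edges into interactome shortest paths →
per-component re-MST → *strong pruning* (a post-order dynamic program that
drops any subtree whose net prize does not pay for its connecting edge),
keeping a component only if its pruned value strictly exceeds $\omega$. The
heuristic is not guaranteed optimal in general; it is verified to match the
exact solver on all oracle-scale random instances, and it never reports an
inconsistent objective (the objective is always recomputed from the returned
node/edge sets).

### 1.3 Stability and specificity

Point solutions of combinatorial problems are brittle. Two filters:

* **Jitter stability**: re-solve with i.i.d. $N(0, \sigma = 0.1)$ noise
  added to edge costs (floored at $10^{-6}$), keep nodes appearing in
  strictly more than `keep_count` of `n_runs` solutions. At $\sigma = 0$ all
  runs coincide, so the kept set must equal the deterministic solution — a
  degeneracy identity used as an acceptance check. Benchmark scale: 30 runs,
  keep > 10; the full-scale convention is 300 / > 100.
* **Degree-preserving specificity null**: draw random terminal sets matching
  the true set's degree-decile profile (a bin lacking candidates is widened
  to its neighbors, with a message), permute the true prizes onto them, and
  re-solve once per draw. Nodes appearing in > 10% (strict) of null
  solutions are flagged as attractors of *any* terminal configuration —
  typically hubs — rather than condition-specific signal. Note an intrinsic
  floor: a node's null frequency is bounded below by its in-bin sampling
  rate (terminals with prize > ω are always kept), so this null is only
  informative when terminals are a small fraction of the interactome; at 100
  randomizations the Monte Carlo standard error at a true rate of 0.08 is
  about 0.027, which the 0.10 cutoff cannot always resolve.

### 1.4 Comparative clustering

The stable node sets of both conditions are pooled; their induced subgraph of
the interactome is trimmed to the largest connected component (node
attributes record origin syn/tau/both and per-condition Steiner status).

Per condition, personalized PageRank with damping $\alpha = 0.85$ runs on the
confidence-weighted pooled graph using that condition's prize weights
(restricted to pooled nodes, renormalized; zero mass falls back to uniform)
as the restart distribution. This smooths each condition's dysregulation onto
the network, giving node vectors $x(v) \in \mathbb{R}^2_{\ge 0}$. Each edge is
weighted by the cosine affinity
$x(u)\!\cdot\!x(v) / (\lVert x(u)\rVert\,\lVert x(v)\rVert)$ — near 1 when
the endpoints share a cross-condition pattern, near 0 when orthogonal.

Louvain community detection runs on these affinities at modularity
resolution $\gamma = 4$,

$$Q_\gamma = \frac{1}{2m} \sum_{ij} \Big[ w_{ij} - \gamma\,
\frac{k_i k_j}{2m} \Big] \delta(c_i, c_j),$$

taking the best-$Q_\gamma$ partition over 100 seeded initializations;
$Q$-ties are broken by the lexicographically smallest canonical partition
signature (cluster IDs relabeled in order of first appearance over sorted
node names), making the selection fully deterministic. Singleton clusters are
discarded with a count. A consequence worth knowing: at $\gamma = 4$ the
modularity optimum favors clusters whose internal degree exceeds roughly
$\gamma$ times the configuration-null expectation, so on *dense* pooled
graphs (small interactomes force density) modules larger than ~8 nodes are
optimally split into pure fragments — the package reports the genuine
optimum rather than post-processing it.

Each cluster is annotated with its lowest-p term by one-sided Fisher's exact
test against the interactome background, over terms with 5–50 background
members (smaller are unstable, larger uninformative); BH is applied across
all cluster × term tests jointly; ties break by smaller term then term ID.
The specificity label is `syn`/`tau`/`both`/`neither` by the strict
"> 30% of cluster nodes at FDR < 0.1 in that condition" rule.

### 1.5 Enrichment, genetics, cell types

* **ORA**: one-sided Fisher $P(X \ge r)$ via the hypergeometric tail, plus
  the z-statistic with finite-population correction
  $z = (r - nR/N)/\sqrt{n f (1-f)(1 - (n-1)/(N-1))}$, $f = R/N$ (the
  classical normal approximation used with a $z \ge 2$ call convention).
* **Preranked GSEA**: weighted Kolmogorov–Smirnov running sum (weight
  exponent 1; hits step by $|s|/\sum_{hits}|s|$, misses by $-1/(N-N_h)$; ES
  is the signed maximum deviation). The null is random same-size gene sets:
  Monte Carlo with add-one correction $p = (1 + \#\{ES^* \ge ES\})/(1+B)$,
  or full enumeration of $\binom{N}{k}$ subsets when requested — small
  backgrounds only, used by the exactness tests.
* **Orthologs/GWAS**: fly→human pairs above a homology-score floor (1–15
  scale), best-per-gene flagged (ties by human ID); intersection with
  gene-level GWAS p-values at a cutoff the caller must supply explicitly —
  there is no scientific default for "GWAS significant" at gene level.
* **Cell types**: a gene belongs to the class (neuronal/glial/unannotated) of
  its maximal-expression reference cluster, ties broken by class priority
  then cluster ID (arbitrary but deterministic). The 3 × 3 class ×
  regulation table is tested by Pearson chi-square without continuity
  correction (df 4); expected cells < 1 raise a warning, not an error.

## 2. The synthetic generator

The generator's role is to produce instances that *have* the structure the
analysis assumes, with a known answer key. Design:

* **Interactome**: preferential-attachment (default) or configuration-model
  graph, largest component, ~300 nodes, mean degree ~6. Edge confidences are
  Beta(4, 2) — unimodal around 0.6–0.8, resembling curated physical-
  interaction score distributions — with four binary evidence-channel flags
  (experimental/database/transferred variants), at least one positive.
* **Modules**: seven disjoint connected subgraphs grown by random-walk
  expansion, then **densified** to mean internal degree 4 by adding
  within-module edges (drawn like any other edge). Densification is
  essential generator realism, not convenience: preferential-attachment
  graphs are locally tree-like, so un-densified "modules" have no more
  internal than external connectivity — no community signal exists for any
  method to find. Dysregulated functional modules in real interactomes are
  protein complexes and pathways, which are locally dense.
* **Patterns**: each module carries one of five condition patterns — syn-only
  up (+e, 0), syn-only down (−e, 0), tau-only (0, +e), shared same-direction
  (+e, +e), shared opposite (+e, −e) — fixing the signed true log2 effect
  per condition (default e = 1).
* **Quantification**: log2 abundance = per-protein baseline N(10, 2) (drawn
  once per seed, shared across conditions, as real protein abundances are) +
  effect in case samples + N(0, 0.3) noise; exported as positive $2^{\log_2}$
  values. 5 control vs 6 case samples per condition.
* **Annotations**: one gene set per planted module plus uniform decoy sets;
  orthologs for 70% of nodes with integer homology scores 1–15 (10% of
  mapped genes get a second, lower-scoring ortholog); GWAS p-values U(0.05,1)
  except ~10 planted mapped genes at U(10⁻⁸, 10⁻⁵) — recoverable at the
  10⁻⁴ convention; a 6-cluster cell-type reference with one dominant cluster
  per gene.

**Limitations (deliberate).** The generator does not model peptide-level
quantification, missing-not-at-random dropout, batch effects, correlated
noise between proteins, or realistic GO term overlap structure; effects are
homogeneous within a module. These are out of scope for what the benchmark
must establish — that each pipeline stage recovers the structure it claims
to recover at honest false-positive rates.

**Known regime limit.** With a ~300-node interactome the pooled comparative
graph is an induced subgraph of a *small dense* network (pooled mean degree
≈ 6 rather than ≈ 3 as in sparse large-interactome settings), and
resolution-4 modularity then optimally fragments 10–12-node modules into
2–4 pure sub-clusters. End-to-end this keeps specificity labels perfect while
capping the adjusted Rand index near ~0.67 — measured and reported, not
corrected by moving generator or clustering parameters.

## 3. Numerical and reproducibility choices

* **Stage seeds**: every random stage derives its seed as a polynomial hash
  of (global seed, stage name) modulo $2^{31}-1$, so toggling one stage never
  shifts another's draws; all hashes stay exact in doubles and valid as R
  seeds. RNG state is saved and restored around every seeded block.
* **Determinism everywhere else**: sorted outputs with documented tie-breaks
  (p then term; score then IDs; partition signatures), so equal-input reruns
  are byte-identical.
* **Strict inequalities** at every threshold; boundary values never pass.
* **Exactness margins**: floating-point comparisons in the solvers use
  $10^{-12}$ slack so branch-and-bound pruning can never discard an optimum
  by rounding; jittered costs are floored at $10^{-6}$ to stay positive.
* **Oracle-first testing**: BH, Fisher, z, chi-square, average-linkage
  clustering, PCSF, and the exhaustive GSEA null are each checked against
  independent brute-force or closed-form re-derivations in the test suite;
  the GSEA statistic is additionally cross-checked against an independent
  external implementation.
* **Text-only exchange formats**: TSV/GMT/YAML/JSON/GraphML throughout; the
  run manifest records package version, derived stage seeds, parameters, and
  MD5 checksums of all inputs.
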