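# pcsfCompare

Comparative proteomic network analysis for two disease conditions profiled
against a shared interactome: differential expression, prize-collecting
Steiner forest (PCSF) network integration with stability and specificity
filtering, cross-condition network clustering, pathway/ortholog/GWAS
integration, and cell-type contingency analysis — plus a synthetic-data
generator that produces fully ground-truthed benchmark instances for all of
it.

## The scientific problem

Quantitative proteomics of two related disease models (here called `syn` and
`tau`) yields, per condition, a protein × sample abundance matrix. The
questions the package answers:

1. Which proteins are dysregulated in each condition, and how much do the two
   conditions overlap?
2. Which *network modules* — connected, functionally coherent subgraphs of a
   confidence-weighted protein–protein interactome — are dysregulated, and
   are they specific to one condition or shared?
3. Do the dysregulated proteins carry independent genetic (GWAS via
   orthology) or cell-type support?

Single-protein lists answer (1) but not (2): module-level signal is spread
over interacting proteins that individually may miss a significance cutoff.
The PCSF formulation recovers such modules by trading off protein-level
evidence against interaction confidence.

## Core method

**Differential expression.** Per protein, a two-sided Welch t-test on
log2 abundances; log2 fold change Δ = mean(case) − mean(control);
Benjamini–Hochberg FDR across proteins.

**Terminals and prizes.** Proteins with q < 0.1 present in the interactome
become terminals with prize

```
p(v) = β · min(|Δ(v)|, 1),          β = 2.
```

**Edge costs.** For interactome edge (u,v) with confidence c ∈ [0,1]:

```
cost(u,v) = (1.5 − c) + γ_hub · (deg u + deg v) / (2 · max degree),   γ_hub = 4,
```

the additive hub penalty discouraging paths through promiscuous hubs.

**PCSF.** Choose a forest F = (V_F, E_F) minimizing

```
Σ_{v terminal ∉ V_F} p(v)  +  Σ_{e ∈ E_F} cost(e)  +  ω · (number of trees),
```

with tree-opening cost ω = 1 (the rooted-reduction virtual-root edge cost).
Instances with ≤ 15 edges are solved exactly by branch-and-bound over acyclic
edge subsets; larger instances use a shortest-path Steiner heuristic
(terminal metric closure → MST against a virtual root → path expansion →
re-MST → strong pruning), which matches the exact optimum on all oracle-scale
test instances.

**Stability.** The PCSF is re-solved `n_runs` times with N(0, σ=0.1) jitter
added to edge costs (floored at 10⁻⁶); nodes detected in strictly more than
`keep_count` runs are kept (benchmark scale: 30 runs, keep > 10).

**Specificity.** Random terminal sets preserving the true set's
degree-decile profile, with permuted prizes, are re-solved once each; a node
appearing in > 10% of random solutions is flagged as non-specific.

**Comparative clustering.** The two conditions' stable node sets are pooled,
their induced interactome subgraph trimmed to the largest component.
Personalized PageRank (damping α = 0.85, per-condition prize weights as the
restart distribution, confidence edge weights) gives each node a smoothed
2-vector x(v) = (x_syn, x_tau); each edge gets the cosine affinity
x(u)·x(v)/(|x(u)||x(v)|). Louvain community detection on these affinities at
modularity resolution γ = 4 (best modularity of 100 seeded initializations,
ties broken by canonical partition signature) yields clusters; singletons are
discarded. Each cluster is annotated with its lowest-p term (one-sided
Fisher, terms of background size 5–50, BH across all cluster × term tests)
and labeled `syn` / `tau` / `both` / `neither` by the strict rule "> 30% of
cluster nodes at FDR < 0.1 in that condition".

**Genetics and cell types.** Significant fly proteins map to human orthologs
(integrated homology score 1–15, best-per-gene flagged) and intersect
gene-level GWAS p-values at a caller-specified cutoff; cell-class assignment
is by maximal reference expression, and the 3 (class) × 3 (up/down/unchanged)
contingency is tested by Pearson chi-square (df = 4, no continuity
correction) — e.g. a statistic of 16.8 gives p = 0.002.

**Synthetic benchmark.** `simConfig()` defaults generate a ~300-node
scale-free interactome with Beta(4,2) edge confidences, seven planted
connected modules (densified to mean internal degree 4, as protein complexes
are) covering five dysregulation patterns (syn-only up/down, tau-only, shared
same/opposite direction), log2 effect 1.0, noise SD 0.3, 5 control vs 6 case
samples per condition, plus matched gene sets, orthologs, GWAS, and
cell-type references. Every generator is a pure function of (config, seed).

## Worked example

```r
library(pcsfCompare)

fix <- makeFixtures(simConfig(n_nodes = 150, seed = 3), "fixtures")
res <- runPipeline(readRunConfig(fix), "results")

head(res$de$syn[order(res$de$syn$q), ], 3)
#>    protein log2FC     t        p        q direction
#> 13   P0013  0.998 10.13 1.00e-05 0.000376        up
#> 38   P0038  1.133 10.85 2.82e-06 0.000376        up
#> 63   P0063  1.100  9.53 9.03e-06 0.000376        up

res$overlap
#>   direction n_syn n_tau overlap background       p
#> 1        up    44    27      14        150 0.00896
#> 2      down    12    10       1        150 0.57731

res$partition
#> ClusterPartition: 58 nodes in 14 clusters (modularity 0.1208)
#>   specificity: both=6, syn=6, tau=2

head(clusterTable(res$partition)[, c("cluster", "size", "term", "fdr", "specificity")], 5)
#>   cluster size      term      fdr specificity
#> 1       1    4 MODULE_01 8.36e-04         syn
#> 2       2    4 MODULE_02 3.99e-04         syn
#> 3       3    5 MODULE_01 6.87e-05         syn
#> 4       4    3 MODULE_03 6.09e-03         tau
#> 5       5    6 MODULE_07 2.15e-08        both

head(res$gwas_hits, 3)
#>   fly_gene human_gene score best direction       gwas_p
#> 1    P0137  HUM_P0137    14 TRUE        up 1.274217e-06
#> 2    P0056  HUM_P0056     9 TRUE        up 4.393865e-06
#> 3    P0123  HUM_P0123     8 TRUE        up 5.477716e-06

rec <- moduleRecovery(res$partition, attr(fix, "objects")$ground_truth)
c(ari = rec$ari, labels = rec$label_accuracy, recovered = rec$recovered_fraction)
#>       ari    labels recovered
#>     0.589     1.000     0.934
```

The recovered clusters are annotated with the planted module gene sets, the
specificity labels match the planted patterns exactly, and the planted
GWAS-enriched orthologs are the only GWAS hits.

A thin CLI wrapper is installed at
`system.file("scripts", "pcsf-compare.R", package = "pcsfCompare")` with
`simulate` and `run` subcommands.

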