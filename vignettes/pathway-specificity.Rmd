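---
title: "Scoring pathway hierarchies for joint evidence around a seed protein"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pathway hierarchies for joint evidence around a seed protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathspec)
```

## The analysis in one paragraph

A regulator protein such as the deubiquitinase USP15 rarely acts on tumor
phenotypes through a single substrate. `pathspec` implements a
coarse-grained alternative to per-gene reasoning: it asks which *pathway
hierarchies* concentrate two independent lines of evidence — genes that
respond to perturbing the regulator (differential expression after a
knockout), and cancer genes that the regulator can plausibly reach through
at most two steps of the protein–protein interaction (PPI) network.
Pathways dense in both are candidates for the regulator's route into
tumorigenesis; their enrichment in functional groups (proliferation,
migration, lipid metabolism) and in the hierarchy's top-level clusters
(signal transduction, cell cycle, DNA repair, ...) is then tested exactly.

## The pathway-hierarchy network

The hierarchy is a directed graph: nodes are pathways (Reactome stable
IDs), arcs point from a parent pathway to a child pathway, as distributed
in Reactome's pathway-relation file. The human hierarchy is a near-forest —
on the order of 2,400 nodes with barely more arcs than nodes — so its
weakly connected components are each anchored by a source node (in-degree
zero, a top-level pathway). `decompose_clusters()` returns exactly these
components as *clusters*, named after their source.

Two edge cases are handled explicitly rather than assumed away. A component
can in principle contain several sources; it is kept as one cluster with
all sources listed, and a warning is raised, because equating components
with single sources is only guaranteed in a forest. A component with no
source (a pure cycle) is retained with an empty source association and
flagged. Gene annotation is taken verbatim from an "all levels"
gene-to-pathway file: no ontology propagation is performed, because the
input format already contains the transitive annotation.

## The three per-node counts and the specificity score

Three gene sets are mapped onto the hierarchy through the annotation map:

* `n_tot` — all annotated genes of the node (the node's mappable universe);
* `n_diff` — annotated genes that passed the differential-expression
  filter, FDR < 0.1 and |log2FC| > 1 (strict inequalities; the
  down-regulated side uses log2FC < −1 symmetrically; a missing FDR is
  never significant);
* `n_HCC` — annotated genes that are cohort cancer genes (mutation
  rate > 1%, strict) *and* layer-1 or layer-2 interactors of the seed
  protein.

Each node is scored

$$s = 10^4 \cdot \frac{n_{diff} \cdot n_{HCC}}{n_{tot}^2},$$

the product of the two evidence fractions, scaled so that a node whose
annotated genes are all simultaneously in both evidence sets reaches
exactly $s = 10^4$. The score is dimensionless and invariant under
proportional scaling of all three counts, so large and small pathways
compete on concentration, not size. A node with both fractions at 4.4%
scores $10^4 \cdot 0.044^2 = 19.36$, just below the default selection
threshold of 20 — the threshold is calibrated to exclude nodes whose
evidence fractions are at the few-percent background level. Selection is
strict (`s > 20`); a node at exactly the threshold is excluded, which makes
the rule deterministic at the boundary. A node with `n_tot = 0` carries no
evidence and scores 0 by definition instead of raising a division error.

Because such score distributions are dominated by zeros,
`score_summary()` reports both conventions — over all nodes and over
nonzero-scoring nodes — rather than choosing one silently.

The high-score sub-network is the *induced* subgraph on the selected
nodes: arcs are kept only if both endpoints are selected. Retaining
non-selected connecting ancestors would change the node count and is
deliberately not done.

## The layered interactome

`bfs_layers()` assigns each protein its unweighted shortest-path distance
from the seed, computed breadth-first: layer 1 is the set of direct
interaction partners, layer 2 the proteins first reachable through a
layer-1 partner. A protein reachable at distances 1 and 2 stays in
layer 1. Self-interactions are recorded by the MITAB parser but never
traversed — a self-loop cannot create a new layer — and edges within a
layer are retained in the network without affecting layer assignment.
The species filter requires the chosen taxon on *both* interactors, and
rows typed as small molecules (MITAB 2.7 interactor-type columns) are
dropped, so compounds never enter the network. The layer assignment is
cross-checked in the test suite against an independent shortest-path
oracle (`igraph::distances`) on random graphs.

## Exact tests and their conventions

All enrichment statements are exact hypergeometric tail sums over the
pathway universe $N$ (all hierarchy nodes, annotated or not): a selection
of $n$ nodes, a category of $K$, an observed overlap $k$, expectation
$Kn/N$. No normal approximation is used anywhere.

Two tail conventions exist in the wild and differ by one term.
`hypergeom_pvalue()` defaults to the inclusive tails $P(X \ge k)$ /
$P(X \le k)$ — the proper p-value convention, which keeps null p-values
super-uniform (verified by simulation in the test suite). The
CDF-complement convention $P(X > k) = 1 - F(k)$, produced when a
spreadsheet's cumulative distribution is subtracted from one, is available
via `inclusive = FALSE`; cluster-enrichment values published with that
convention can only be reproduced with it, so the flag is explicit rather
than hidden. Depletion (under-representation, as for lipid-process
pathways) is the inclusive lower tail.

Raw p-values are reported by default across the handful of functional sets
and the 28 clusters, matching how small planned families of tests are
usually published; Benjamini–Hochberg adjustment is available through
`adjust_enrichment()`.

The clinical module reconstructs 2×2 tables from printed cohort
percentages (`counts_from_percent()`, nearest-integer rounding
half-away-from-zero, checked against printed row totals) and tests them
with a from-scratch two-tailed Fisher exact test: the p-value is the sum
of the point probabilities of every margin-preserving table whose
probability does not exceed the observed one (point-probability
criterion), with a `1 + 1e-7` relative guard against floating-point ties —
the same guard base R uses. The routine is validated against brute-force
enumeration and `fisher.test()`.

## What the synthetic generator emulates

`simulate_study()` produces every input file the pipeline consumes, from
one master seed, with the planted truth recorded:

* **Hierarchy** — components are random rooted trees; extra arcs go only
  from lower to higher depth within a component, so the roots remain the
  only sources and the truth (membership, sources) holds by construction.
  The study-scale preset uses the 28 printed top-level cluster sizes of
  the human hierarchy (2,369 nodes; `reactome_cluster_sizes()`) with
  extra arcs tuned so the arc count sits just above the node count, the
  near-forest regime of the real data.
* **Annotation** — per-node gene counts from a log-normal sampler
  calibrated to median ≈ 17 and mean ≈ 56 genes per node, the
  right-skewed regime observed when all human genes are mapped to the
  hierarchy; genes are shared across nodes.
* **Evidence sets** — genes annotated to one planted cluster are drawn
  with odds multiplied by a boost factor (boost 1 = null). The study-scale
  sizes are 481 differential genes (203 up + 278 down among 14,099) and
  143 cancer-interactome genes, plus 152 decoy cancer genes kept outside
  the interactome so that the mutation-rate filter yields 295 candidates
  of which exactly 143 are reachable.
* **Interactome** — 105 layer-1 and 6,175 layer-2 proteins with extra
  edges never incident to the seed (so no shortcut can change a layer),
  about 17,400 edges, emitted as valid PSI-MITAB 2.5 rows.
* **DE table** — planted genes receive |log2FC| ≥ effect and FDR < 0.1,
  background genes centered noise with FDR ≥ 0.1, so the filter recovers
  the planted sets exactly; this is simulation at the summary-statistic
  level, not read-level RNA-seq simulation.

What passing tests on these data do *not* show: real annotation bias
(large metabolic pathways are not random gene draws), correlated evidence
(differential expression and mutation status co-occur in real tumors in
ways the independent samplers do not model), interaction-detection bias in
PPI databases, and identifier-mapping loss between UniProt accessions and
gene symbols. The generator validates the machinery, not the biology.

## Problem sizes and runtime choices

The test suite runs the full property set at a reduced scale chosen so the
whole suite finishes in well under two minutes: a 124-node, 8-component
hierarchy with a 1,500-gene universe, a 30/220-protein interactome, and
100 replanting runs for the planted-recovery property (boost 10, observed
recovery ≥ 95/100). Null calibration uses 2,500 simulated random
selections at the full 2,423-node universe, which is cheap because the
overlap distribution is sampled directly. The acceptance script runs the
complete study-scale simulation (2,369 nodes, 14,099 genes, 6,280-protein
interactome) in a few seconds.

## Open design choices, resolved

* The pipeline surface is the set of exported functions plus
  `pipeline_config()`/`run_pipeline()`/`report()`; a YAML configuration
  file is supported for file-based runs. No shell entry point is shipped —
  the package is an analysis library, not a command-line tool.
* Published node counts for the human hierarchy drift across database
  releases (2,423 vs 2,443 in different places; the printed cluster sizes
  sum to 2,369). All such sizes are treated as data-dependent, never as
  constants; the generator presets simply pick one consistent instance.
* Percentages in reports are printed with one decimal; a selection of 225
  from 2,423 prints as 9.3%.
* Dispersions reported alongside means (annotation counts, scores) are
  population-style standard deviations.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_study("test", seed = 1)
cfg <- pipeline_config(relations = sim$network,
                       annotations = sim$annotations,
                       mitab = sim$interactome$records,
                       de = sim$de$table,
                       cancer = sim$cancer_table)
res <- run_pipeline(cfg)
report(res)
res$clusters[order(res$clusters$p_upper), ]
```

## Known limitations

Enrichment treats pathway nodes as exchangeable units, although nested
hierarchies make nearby nodes highly dependent; cluster-level tests
partially absorb this but p-values within a cluster family remain
correlated. The score has no uncertainty attached — a node with
`n_tot = 1` and one double-evidence gene scores the maximal 10^4 — so
selections should be read together with the underlying counts, which the
score table always carries.
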