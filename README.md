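# pathspec

Pathway-hierarchy specificity scoring and enrichment for seed-protein
interactomes.

## The problem

When a regulator protein (the motivating case is the deubiquitinase USP15
in hepatocellular carcinoma) influences a phenotype through many indirect
interactions, per-gene analyses fragment the signal. `pathspec` works at
the level of *pathway hierarchies* instead: it builds the directed
parent–child network of pathways (Reactome-style relation files),
decomposes it into its source-rooted clusters, and asks which pathway
nodes concentrate two independent gene evidence sets —

* **differential-expression hits** from perturbing the regulator
  (FDR < 0.1, |log2FC| > 1), and
* **cancer genes** (cohort mutation rate > 1%) that are reachable from the
  seed protein within two layers of the protein–protein interaction
  network (breadth-first shortest-path layers over PSI-MITAB records).

Each pathway node with `n_tot` annotated genes, of which `n_diff` are
differential hits and `n_HCC` are cancer-interactome genes, receives the
specificity score

```
s = 10^4 * n_diff * n_HCC / n_tot^2
```

which reaches its theoretical upper bound `s = 10^4` when every annotated
gene carries both kinds of evidence, and stays below the default selection
threshold of 20 when both evidence fractions are at the few-percent
background level (both at 4.4% gives s = 19.36). The high-score selection
(`s > 20`, strict) is then tested for exact hypergeometric enrichment or
depletion of functional pathway sets and of the hierarchy's clusters. A
from-scratch two-tailed Fisher exact test for clinical 2×2 tables
(reconstructed from printed cohort percentages) and the caliper
tumor-volume formula `0.5 * length * width^2` round out the toolkit.

A synthetic-data module generates every input the pipeline consumes —
hierarchy, annotations, interactome, DE table, cancer-gene table — with
planted ground truth, so the whole analysis is testable offline.

## Worked example

```r
library(pathspec)

sim <- simulate_study("test", seed = 1)   # small synthetic study
cfg <- pipeline_config(relations   = sim$network,
                       annotations = sim$annotations,
                       mitab       = sim$interactome$records,
                       de          = sim$de$table,
                       cancer      = sim$cancer_table)
res <- run_pipeline(cfg)
report(res)
```

```
Pathway hierarchy: 124 nodes, 125 arcs, 8 clusters
Interactome of 'USP15': 30 layer-1 and 220 layer-2 proteins, 375 edges
Differentially expressed genes: 45 up, 45 down
Cancer genes in the interactome: 60
Score over all nodes: median 0, mean 419 +/- 1e+03, max 7.5e+03
Score over nonzero nodes: median 1.11e+03, mean 1.33e+03 +/- 1.4e+03 (n = 39)
Selected 39 of 124 nodes (31.5%)
Enriched clusters: 1 of 8
Cluster 'R-SYN-000056': 17 of 20 selected (85.00%), p = 8.764e-08
```

The one enriched cluster, `R-SYN-000056`, is exactly the cluster in which
the generator planted the evidence (`sim$truth$planted_cluster`): the two
gene sets were drawn with 10-fold odds for genes annotated there, the
score concentrates on its nodes, and the exact upper-tail hypergeometric
test ranks it first. The score table carries the per-node counts behind
every selection:

```r
head(res$scores[order(-res$scores$s), ], 3)
#>         pathway n_tot n_diff n_hcc        s selected
#> 69 R-SYN-000069     4      4     3 7500.000     TRUE
#> 67 R-SYN-000067     5      4     2 3200.000     TRUE
#> 72 R-SYN-000072     5      2     4 3200.000     TRUE
```

The individual stages are exported (`parse_relations()`,
`read_annotations()`, `parse_mitab()`, `bfs_layers()`,
`intersect_network_genes()`, `filter_de()`, `filter_mutation_rate()`,
`count_node_genes()`, `score_all()`, `select_high_score()`,
`functional_enrichment()`, `cluster_enrichment()`,
`fisher_exact_two_tail()`, ...), and the exact tail routines are directly
usable:

```r
hypergeom_pvalue(2423, 143, 225, 7, tail = "lower")
#> [1] 0.035359066   # depletion of a 143-pathway set overlapping only 7
fisher_exact_two_tail(matrix(c(38, 9, 38, 17), 2, byrow = TRUE))
#> [1] 0.2543291
```

## Documentation

The methods vignette (`vignettes/pathway-specificity.Rmd`) describes the
model, the tail-probability conventions, the synthetic generator's
calibration, and the design decisions in detail.
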