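# Generator determinism and structural guarantees.

test_that("gen_hierarchy builds the requested near-forest", {
  g <- gen_hierarchy(c(10L, 6L, 1L), extra_arc_fraction = 0.2, seed = 4)
  net <- g$network
  expect_equal(length(net$nodes), 17L)
  expect_setequal(find_source_nodes(net), g$truth$sources)
  expect_length(g$truth$sources, 3L)
  part <- decompose_clusters(net)
  expect_equal(length(part$clusters), 3L)
  # membership truth matches the decomposition
  for (cl in part$clusters) {
    expect_equal(length(unique(g$truth$membership[cl])), 1L)
  }
  expect_error(gen_hierarchy(c(3L, 0L)), ">= 1")

  solo <- gen_hierarchy(1L, 0, seed = 1)
  expect_equal(length(solo$network$nodes), 1L)
  expect_equal(nrow(solo$network$arcs), 0L)
})

test_that("the study-scale preset reproduces the component structure", {
  g <- gen_hierarchy(seed = 8)
  expect_equal(length(g$network$nodes), sum(reactome_cluster_sizes()))
  expect_length(find_source_nodes(g$network), 28L)
  expect_equal(length(decompose_clusters(g$network)$clusters), 28L)
  # near-forest: extra arcs put the arc count just above nodes - components
  expect_equal(nrow(g$network$arcs),
               length(g$network$nodes) - 28L +
                 round(0.012 * length(g$network$nodes)))
})

test_that("generators are deterministic in their seed", {
  a <- gen_hierarchy(c(8L, 5L), 0.1, seed = 99)
  b <- gen_hierarchy(c(8L, 5L), 0.1, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a$network$arcs,
                         gen_hierarchy(c(8L, 5L), 0.1, seed = 100)$network$arcs))

  d1 <- gen_de_table(200, 5, 5, seed = 3)
  d2 <- gen_de_table(200, 5, 5, seed = 3)
  expect_identical(d1, d2)

  i1 <- gen_interactome(layer1_size = 5, layer2_size = 12,
                        extra_edge_fraction = 0.3, seed = 21)
  i2 <- gen_interactome(layer1_size = 5, layer2_size = 12,
                        extra_edge_fraction = 0.3, seed = 21)
  expect_identical(i1$records, i2$records)

  # generators restore the caller's RNG state
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(gen_hierarchy(c(4L), seed = 5)); y <- runif(1)
  expect_identical(x, y)
})

test_that("gen_annotations hits the heavy-tailed calibration targets", {
  g <- gen_hierarchy(seed = 1)
  ann <- gen_annotations(g$network, seed = 2)
  counts <- count_node_genes(g$network, ann)
  s <- summarize_counts(counts)
  expect_gte(s$median, 12); expect_lte(s$median, 22)
  expect_gte(s$mean, 45); expect_lte(s$mean, 70)
  expect_gt(s$mean, s$median)  # right-skewed

  tiny <- gen_hierarchy(c(5L), seed = 1)
  one_each <- gen_annotations(tiny$network, universe_size = 50, seed = 3,
                              count_sampler = function(n) rep(1L, n))
  expect_true(all(count_node_genes(tiny$network, one_each) == 1L))

  same_gene <- gen_annotations(tiny$network, universe_size = 1, seed = 4)
  expect_equal(names(same_gene$gene2path), "G00001")
})

test_that("gen_interactome plants exact layer sizes", {
  sim <- gen_interactome(layer1_size = 20, layer2_size = 70,
                         extra_edge_fraction = 0.8, seed = 13)
  rec <- suppressMessages(parse_mitab(sim$records))
  lay <- bfs_layers(rec, "USP15")
  expect_setequal(names(lay$layer)[lay$layer == 1L], sim$truth$layer1)
  expect_setequal(names(lay$layer)[lay$layer == 2L], sim$truth$layer2)

  star <- gen_interactome(layer1_size = 3, layer2_size = 0,
                          extra_edge_fraction = 0, seed = 1)
  expect_length(star$records, 3L)
  expect_error(gen_interactome(layer1_size = 0, layer2_size = 5),
               "layer 1")

  # contaminant rows are removed by the species filter
  dirty <- gen_interactome(layer1_size = 6, layer2_size = 10,
                           extra_edge_fraction = 0, seed = 2,
                           contaminants = 4)
  rec2 <- suppressMessages(parse_mitab(dirty$records))
  expect_equal(nrow(rec2), 16L)
  expect_false(any(grepl("YEAST", c(rec2$a, rec2$b))))
})

test_that("gen_interactome honors include genes and node pools", {
  pool <- sprintf("GENE%03d", 1:200)
  must <- c("GENE001", "GENE002", "GENE003")
  sim <- gen_interactome(layer1_size = 10, layer2_size = 40,
                         extra_edge_fraction = 0, seed = 5,
                         node_pool = pool, include = must)
  members <- c(sim$truth$layer1, sim$truth$layer2)
  expect_true(all(must %in% members))
  expect_true(all(members %in% pool))
})

test_that("gen_de_table warns on weak effects and respects explicit sets", {
  expect_warning(gen_de_table(100, 2, 2, effect = 0.8, seed = 1),
                 "effect")
  g <- gen_de_table(genes = sprintf("g%02d", 1:50),
                    up_genes = c("g01", "g02"), down_genes = "g10",
                    seed = 6)
  sets <- filter_de(g$table)
  expect_setequal(sets$up, c("g01", "g02"))
  expect_setequal(sets$down, "g10")
  expect_error(gen_de_table(genes = sprintf("g%02d", 1:50),
                            up_genes = "g01", down_genes = "g01"),
               "overlap")

  none <- gen_de_table(100, 0, 0, seed = 1)
  expect_equal(lengths(filter_de(none$table)), c(up = 0L, down = 0L))
})

test_that("gen_cancer_table plants recoverable high-rate genes", {
  genes <- sprintf("g%03d", 1:300)
  planted <- sample(genes, 40)
  tab <- gen_cancer_table(genes, planted, seed = 3)
  expect_setequal(filter_mutation_rate(tab, 1), planted)
})

test_that("gen_query_sets boosts planted-cluster genes and checks sizes", {
  g <- gen_hierarchy(c(20L, 20L), 0, seed = 1)
  part <- decompose_clusters(g$network)
  ann <- gen_annotations(g$network, universe_size = 400, seed = 2,
                         count_sampler = function(n) rep(10L, n))
  expect_error(gen_query_sets(ann, part, set_sizes = c(1e6, 1)),
               "exceeds")
  expect_error(gen_query_sets(ann, part, planted_cluster = "nope",
                              boost = 2, set_sizes = c(10, 5)),
               "not in the partition")
  qs0 <- gen_query_sets(ann, part, set_sizes = c(0, 0), seed = 1)
  expect_length(qs0$diff, 0L)

  planted <- names(part$clusters)[1]
  in_planted <- unique(unlist(ann$path2gene[part$clusters[[planted]]]))
  hits <- replicate(20, {
    qs <- gen_query_sets(ann, part, planted_cluster = planted, boost = 25,
                         set_sizes = c(40, 0), seed = sample.int(1e6, 1))
    mean(qs$diff %in% in_planted)
  })
  null_frac <- mean(names(ann$gene2path) %in% in_planted)
  expect_gt(mean(hits), null_frac)
})

test_that("simulate_study wires consistent inputs with recorded truth", {
  sim <- simulate_study("test", seed = 3)
  expect_setequal(find_source_nodes(sim$network),
                  sim$truth$hierarchy$sources)
  sets <- filter_de(sim$de$table)
  expect_setequal(sets$up, sim$truth$de$up)
  expect_setequal(sets$down, sim$truth$de$down)
  expect_setequal(filter_mutation_rate(sim$cancer_table, 1),
                  sim$truth$cancer)
  rec <- suppressMessages(parse_mitab(sim$interactome$records))
  lay <- bfs_layers(rec, sim$seed_protein)
  expect_setequal(names(lay$layer)[lay$layer == 1L], sim$truth$layer1)
  expect_setequal(names(lay$layer)[lay$layer == 2L], sim$truth$layer2)
  # the planted cancer genes are exactly the cohort genes inside the network
  expect_setequal(intersect_network_genes(lay, sim$truth$cancer),
                  sim$truth$hcc)
})
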