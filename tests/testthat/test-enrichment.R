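# Hypergeometric enrichment of functional sets and hierarchy clusters.

test_that("expected_count is K*n/N with guarded input", {
  expect_equal(round(expected_count(163, 225, 2423), 2), 15.14)
  expect_equal(round(expected_count(75, 225, 2423), 2), 6.96)
  expect_equal(round(expected_count(143, 225, 2423), 2), 13.28)
  expect_error(expected_count(1, 1, 0), "N")
})

test_that("hypergeom_pvalue matches direct enumeration on a small case", {
  # C(4,3)C(6,2) + C(4,4)C(6,1) over C(10,5)
  expect_equal(hypergeom_pvalue(10, 4, 5, 3, "upper"), 66 / 252)
  expect_equal(hypergeom_pvalue(10, 4, 5, 0, "upper"), 1)
  p0 <- hypergeom_pvalue(10, 4, 5, 0, "lower")
  expect_equal(p0, choose(6, 5) / choose(10, 5))
  expect_error(hypergeom_pvalue(10, 4, 5, 6, "upper"), "inconsistent")
})

test_that("hypergeom_pvalue matches the exhaustive oracle for all N <= 12", {
  for (N in 1:12) {
    for (K in 0:N) {
      for (n in 0:N) {
        ks <- 0:min(K, n)
        for (k in ks) {
          expect_equal(hypergeom_pvalue(N, K, n, k, "upper"),
                       hyper_tail_oracle(N, K, n, k, "upper"),
                       tolerance = 1e-12)
          expect_equal(hypergeom_pvalue(N, K, n, k, "lower"),
                       hyper_tail_oracle(N, K, n, k, "lower"),
                       tolerance = 1e-12)
          expect_equal(hypergeom_pvalue(N, K, n, k, "upper",
                                        inclusive = FALSE),
                       hyper_tail_oracle(N, K, n, k, "upper",
                                         inclusive = FALSE),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("upper and lower tails are complementary", {
  cases <- expand.grid(N = c(20, 57, 101), frac_K = c(0.2, 0.5),
                       frac_n = c(0.1, 0.6))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]
    K <- round(cases$frac_K[i] * N)
    n <- round(cases$frac_n[i] * N)
    for (k in seq_len(min(K, n))) {
      expect_equal(hypergeom_pvalue(N, K, n, k, "upper") +
                     hypergeom_pvalue(N, K, n, k - 1, "lower"),
                   1, tolerance = 1e-12)
    }
  }
})

test_that("functional_enrichment reports both tails and flags depletion", {
  universe <- sprintf("P%04d", 1:2423)
  sel <- universe[1:225]
  lipid_like <- c(universe[1:7], universe[300:435])  # K = 143, overlap 7
  res <- functional_enrichment(sel, list(lipid = lipid_like), universe)
  expect_equal(res$K, 143L)
  expect_equal(res$k, 7L)
  expect_equal(res$expected, 143 * 225 / 2423)
  expect_equal(res$p_lower, 0.035359066, tolerance = 1e-7)
  expect_true(res$depleted)

  disjoint <- functional_enrichment(sel, list(none = "NOT-THERE"), universe)
  expect_equal(disjoint$K, 0L)
  expect_equal(disjoint$p_upper, 1)

  everything <- functional_enrichment(universe, list(s = universe[1:10]),
                                      universe)
  expect_equal(everything$p_upper, 1)  # degenerate draw-all case

  expect_error(functional_enrichment("a", list(x = "a"), character(0)),
               "empty universe")
})

test_that("cluster overlaps sum to the selection size", {
  g <- gen_hierarchy(c(12L, 20L, 8L), extra_arc_fraction = 0, seed = 2)
  part <- decompose_clusters(g$network)
  set.seed(9)
  sel <- sample(g$network$nodes, 11)
  res <- cluster_enrichment(sel, part, g$network$nodes)
  expect_equal(sum(res$k), 11L)
  expect_true(all(res$percent >= 0 & res$percent <= 100))
  zero <- res[res$k == 0, ]
  if (nrow(zero) > 0) {
    expect_true(all(zero$p_upper == 1))
    expect_true(all(!zero$enriched))
  }
  # clusters must partition the universe
  expect_error(cluster_enrichment(sel, part, c(g$network$nodes, "EXTRA")),
               "partition")
})

test_that("null upper-tail p-values are super-uniform", {
  # under a uniformly random selection the overlap is hypergeometric;
  # the fraction of p < 0.05 must stay at or below nominal
  set.seed(2026)
  N <- 2423; K <- 143; n <- 225
  k <- rhyper(2000, K, N - K, n)
  p <- vapply(k, function(ki) hypergeom_pvalue(N, K, n, ki, "upper"),
              numeric(1))
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("a boosted cluster attains the smallest enrichment p-value", {
  # fixed hierarchy + annotation; re-plant the evidence sets 100 times
  g <- gen_hierarchy(c(30L, 25L, 20L, 15L, 12L, 10L, 8L, 4L),
                     extra_arc_fraction = 9 / 124, seed = 11)
  part <- decompose_clusters(g$network)
  ann <- gen_annotations(g$network, universe_size = 1500, seed = 12,
                         count_sampler = function(n) pmax(1L, rpois(n, 6)))
  planted <- names(part$clusters)[which.max(lengths(part$clusters))]
  n_tot <- count_node_genes(g$network, ann)
  wins <- 0L
  for (run_seed in 1:100) {
    qs <- gen_query_sets(ann, part, planted_cluster = planted, boost = 10,
                         set_sizes = c(90, 60), seed = run_seed)
    n_diff <- suppressMessages(count_node_genes(g$network, ann, qs$diff))
    n_hcc <- suppressMessages(count_node_genes(g$network, ann, qs$hcc))
    tab <- score_all(g$network, n_tot, n_diff, n_hcc)
    sel <- suppressWarnings(suppressMessages(select_high_score(tab)))
    res <- cluster_enrichment(sel, part, g$network$nodes)
    if (res$cluster[which.min(res$p_upper)] == planted) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("adjust_enrichment appends BH-corrected p-values", {
  res <- data.frame(p_upper = c(0.01, 0.02, 0.5))
  adj <- adjust_enrichment(res)
  expect_equal(adj$p_upper_bh, p.adjust(res$p_upper, "BH"))
})
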