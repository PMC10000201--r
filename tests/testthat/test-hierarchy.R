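# Hierarchy parsing, source nodes, cluster decomposition, gene counting.

test_that("parse_relations builds nodes and deduplicated arcs", {
  net <- suppressMessages(parse_relations(c("A B", "A C")))
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$arcs), 2L)

  dup <- suppressMessages(parse_relations(c("A\tB", "A\tB")))
  expect_equal(length(dup$nodes), 2L)
  expect_equal(nrow(dup$arcs), 1L)

  three <- suppressMessages(parse_relations(c("A B", "B C", "D E")))
  expect_equal(length(three$nodes), 5L)
  expect_equal(nrow(three$arcs), 3L)
  expect_equal(length(decompose_clusters(three)$clusters), 2L)
})

test_that("parse_relations rejects malformed lines and warns on empty input", {
  expect_error(parse_relations(c("A B", "C")), "line 2")
  expect_error(parse_relations("A B C"), "3")
  expect_warning(parse_relations(""), "empty")
  empty <- suppressWarnings(parse_relations(""))
  expect_equal(length(empty$nodes), 0L)
})

test_that("relation files round-trip through write and re-parse", {
  net <- tiny_hierarchy()
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%s\t%s", net$arcs$parent, net$arcs$child), f)
  again <- suppressMessages(parse_relations(f))
  expect_setequal(again$nodes, net$nodes)
  expect_equal(again$arcs[order(again$arcs$parent, again$arcs$child), ],
               net$arcs[order(net$arcs$parent, net$arcs$child), ],
               ignore_attr = TRUE)
})

test_that("find_source_nodes returns exactly the in-degree-zero nodes", {
  chain <- hierarchy_network(rbind(c("A", "B"), c("B", "C")))
  expect_equal(find_source_nodes(chain), "A")

  two <- hierarchy_network(rbind(c("A", "B"), c("C", "D")))
  expect_setequal(find_source_nodes(two), c("A", "C"))

  diamond <- hierarchy_network(rbind(c("A", "B"), c("A", "C"),
                                     c("B", "D"), c("C", "D")))
  expect_equal(find_source_nodes(diamond), "A")
})

test_that("decompose_clusters partitions nodes into source-rooted components", {
  net <- tiny_hierarchy()
  part <- decompose_clusters(net)
  expect_equal(length(part$clusters), 2L)
  # partition property: disjoint and covering
  all_nodes <- unlist(part$clusters, use.names = FALSE)
  expect_equal(sort(all_nodes), sort(net$nodes))
  expect_equal(anyDuplicated(all_nodes), 0L)
  # each cluster named after and containing its source
  expect_setequal(names(part$clusters), c("A", "X"))
  expect_true(all(mapply(`%in%`, names(part$sources), part$clusters)))

  single <- hierarchy_network(NULL, nodes = "solo")
  psingle <- decompose_clusters(single)
  expect_equal(psingle$clusters[[1]], "solo")
  expect_equal(psingle$sources[[1]], "solo")
})

test_that("a pure cycle is retained as a cluster with no source", {
  net <- hierarchy_network(rbind(c("A", "B"), c("B", "A")))
  expect_warning(decompose_clusters(net), "no source")
  part <- suppressWarnings(decompose_clusters(net))
  expect_equal(length(part$clusters), 1L)
  expect_equal(length(part$sources[[1]]), 0L)
})

test_that("every source lies in exactly one cluster on random forests", {
  for (seed in 1:5) {
    g <- gen_hierarchy(c(6L, 9L, 4L, 11L), extra_arc_fraction = 0.1,
                       seed = seed)
    part <- decompose_clusters(g$network)
    sources <- find_source_nodes(g$network)
    expect_setequal(sources, g$truth$sources)
    expect_equal(length(part$clusters), 4L)
    hit <- vapply(sources, function(s) {
      sum(vapply(part$clusters, function(cl) s %in% cl, logical(1)))
    }, integer(1))
    expect_true(all(hit == 1L))
    expect_equal(sum(lengths(part$clusters)), length(g$network$nodes))
  }
})

test_that("count_node_genes counts annotated genes within a gene set", {
  net <- tiny_hierarchy()
  ann <- tiny_annotation()
  expect_message(count_node_genes(net, ann, c("g2", "g3", "g9")), "1 of 3")
  counts <- suppressMessages(count_node_genes(net, ann, c("g2", "g3", "g9")))
  expect_equal(counts[["A"]], 2L)
  expect_equal(counts[["B"]], 0L)

  expect_equal(sum(count_node_genes(net, ann, character(0))), 0L)

  tot <- count_node_genes(net, ann)
  expect_equal(tot[["A"]], 3L)
  expect_equal(tot[["B"]], 2L)
  expect_equal(tot[["D"]], 0L)  # unannotated node
})

test_that("summarize_counts summarizes mapped nodes only", {
  s <- summarize_counts(c(a = 1, b = 2, c = 3))
  expect_equal(s[c("min", "max", "median", "mean")],
               list(min = 1, max = 3, median = 2, mean = 2))
  s1 <- summarize_counts(c(a = 5))
  expect_equal(s1$sd, 0)
  expect_equal(s1$mean, 5)
  s2 <- summarize_counts(c(a = 0, b = 0, c = 4))
  expect_equal(s2$n_nonzero, 1L)
  expect_equal(s2$min, 4)
  expect_error(summarize_counts(c(a = 0, b = 0)), "no mapped nodes")
})

test_that("network exports are importable text formats", {
  net <- tiny_hierarchy()
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), nrow(net$arcs))
  expect_true(all(grepl("\tparent_of\t", lines)))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  expect_true(any(grepl("graphml", readLines(gml))))
})
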