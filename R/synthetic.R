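# Synthetic-data generators: every input the pipeline consumes, produced
# with known ground truth so each stage can be tested without database
# downloads. Every generator is a pure function of its parameters and seed.

#' Sizes of the 28 top-level clusters of the human pathway hierarchy
#'
#' The printed sizes of the 28 weakly connected components of the human
#' Reactome pathway-hierarchy network (release circa mid-2020), named by
#' their top-level pathway. Used as the default component-size preset of
#' [gen_hierarchy()] so that study-scale simulations reproduce the real
#' hierarchy's component structure.
#'
#' @return Named integer vector of length 28 summing to 2369.
#' @export
reactome_cluster_sizes <- function() {
  c("Hemostasis" = 39L,
    "Intrinsic pathway for Apoptosis" = 20L,
    "Neuronal System" = 78L,
    "Developmental Biology" = 59L,
    "Metabolism" = 325L,
    "Reproduction" = 8L,
    "Extracellular matrix organization" = 19L,
    "Cell-Cell communication" = 13L,
    "Signal Transduction" = 382L,
    "Cell Cycle" = 122L,
    "Disease" = 517L,
    "Immune System" = 197L,
    "Organelle biogenesis and maintenance" = 13L,
    "Transport of small molecules" = 69L,
    "Metabolism of proteins" = 124L,
    "Muscle contraction" = 11L,
    "Circadian Clock" = 4L,
    "Chromatin organization" = 7L,
    "Programmed Cell Death" = 21L,
    "Vesicle-mediated transport" = 38L,
    "DNA Replication" = 19L,
    "DNA Repair" = 61L,
    "Gene expression (Transcription)" = 125L,
    "Metabolism of RNA" = 51L,
    "Cellular responses to external stimuli" = 24L,
    "Digestion and absorption" = 7L,
    "Protein localization" = 6L,
    "Autophagy" = 10L)
}

#' Generate a near-forest pathway hierarchy with known components
#'
#' Each component is a random rooted tree (node i attaches to a uniformly
#' chosen earlier node), after which extra arcs are added only within a
#' component and only from a lower-depth node to a higher-depth node. Roots
#' therefore remain the only in-degree-zero nodes, no cycles can arise, and
#' the true component membership and source set are recorded as ground
#' truth. `extra_arc_fraction` is the number of extra arcs per network node;
#' the study-scale hierarchy (arcs = nodes + 1 across 28 components) needs
#' about 0.012.
#'
#' @param component_sizes integer vector of component sizes (each >= 1);
#'   defaults to [reactome_cluster_sizes()].
#' @param extra_arc_fraction extra arcs per node, >= 0.
#' @param seed random seed.
#' @return List with `network` (a [hierarchy_network()]) and `truth` (list
#'   with `membership` — named component index per node — `sources`,
#'   `component_sizes`, `seed`).
#' @export
gen_hierarchy <- function(component_sizes = reactome_cluster_sizes(),
                          extra_arc_fraction = 0.012, seed = 1) {
  if (any(component_sizes < 1)) stop("component sizes must be >= 1")
  stopifnot(extra_arc_fraction >= 0)
  local_seed(seed, {
    n <- sum(component_sizes)
    ids <- sprintf("R-SYN-%06d", seq_len(n))
    comp_of <- rep(seq_along(component_sizes), component_sizes)
    names(comp_of) <- ids
    offsets <- cumsum(c(0L, utils::head(component_sizes, -1L)))
    parent <- child <- character(0)
    depth <- integer(n)
    roots <- character(length(component_sizes))
    for (ci in seq_along(component_sizes)) {
      m <- component_sizes[ci]
      base <- offsets[ci]
      roots[ci] <- ids[base + 1L]
      if (m == 1L) next
      par_idx <- integer(m)
      for (i in 2:m) {
        p <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
        par_idx[i] <- p
        depth[base + i] <- depth[base + p] + 1L
      }
      parent <- c(parent, ids[base + par_idx[2:m]])
      child <- c(child, ids[base + 2:m])
    }
    arcs <- data.frame(parent = parent, child = child,
                       stringsAsFactors = FALSE)
    n_extra <- round(extra_arc_fraction * n)
    if (n_extra > 0) {
      have <- paste(arcs$parent, arcs$child)
      added <- 0L
      tries <- 0L
      non_root <- which(depth > 0L)
      while (added < n_extra && tries < 200L * n_extra &&
             length(non_root) > 0L) {
        tries <- tries + 1L
        v <- non_root[sample.int(length(non_root), 1L)]
        cand <- which(comp_of == comp_of[v] & depth < depth[v])
        cand <- setdiff(cand, v)
        if (length(cand) == 0L) next
        u <- cand[sample.int(length(cand), 1L)]
        key <- paste(ids[u], ids[v])
        if (key %in% have) next
        arcs <- rbind(arcs, data.frame(parent = ids[u], child = ids[v],
                                       stringsAsFactors = FALSE))
        have <- c(have, key)
        added <- added + 1L
      }
    }
    net <- hierarchy_network(arcs, nodes = ids)
    list(network = net,
         truth = list(membership = comp_of, sources = roots,
                      component_sizes = as.integer(component_sizes),
                      seed = seed))
  })
}

#' Generate heavy-tailed gene annotations for a hierarchy
#'
#' Per-node annotation counts are drawn from a log-normal sampler whose
#' defaults give a median around 17 and a mean around 56 genes per node, the
#' strongly right-skewed regime of real pathway annotation (median well
#' below mean). Genes are sampled with replacement across nodes, so a gene
#' typically annotates several pathways.
#'
#' @param net a [hierarchy_network()].
#' @param universe_size number of distinct genes available, default 14099.
#' @param seed random seed.
#' @param meanlog,sdlog log-normal parameters of the per-node count sampler.
#' @param count_sampler optional function(n) returning n positive integers,
#'   overriding the log-normal sampler.
#' @return An [annotation_map()] with the full gene universe attached as
#'   `attr(, "universe")`.
#' @export
gen_annotations <- function(net, universe_size = 14099, seed = 1,
                            meanlog = log(17), sdlog = 1.55,
                            count_sampler = NULL) {
  stopifnot(inherits(net, "hierarchy_network"), universe_size >= 1)
  local_seed(seed, {
    genes_all <- sprintf("G%05d", seq_len(universe_size))
    n_nodes <- length(net$nodes)
    counts <- if (is.null(count_sampler)) {
      pmax(1L, as.integer(round(stats::rlnorm(n_nodes, meanlog, sdlog))))
    } else {
      as.integer(count_sampler(n_nodes))
    }
    counts <- pmin(counts, universe_size)
    gene <- unlist(lapply(counts, function(k) {
      genes_all[sample.int(universe_size, k)]
    }), use.names = FALSE)
    pathway <- rep(net$nodes, counts)
    ann <- annotation_map(gene, pathway, namespace = "synthetic")
    attr(ann, "universe") <- genes_all
    ann
  })
}

#' Generate the two gene evidence sets with a planted enriched cluster
#'
#' Draws a differential-expression-like gene set and a cancer-like gene set
#' from the annotated gene universe. Genes annotated to any node of the
#' planted cluster are sampled with probability proportional to `boost`,
#' all others proportional to 1, so downstream scoring and cluster
#' enrichment should recover the planted cluster; `boost = 1` is the null.
#'
#' @param ann an [annotation_map()] (typically from [gen_annotations()]).
#' @param clusters a `cluster_partition` from [decompose_clusters()].
#' @param planted_cluster cluster identifier to boost, or `NULL` for none.
#' @param boost sampling-odds multiplier, >= 1.
#' @param set_sizes lengths of the (diff-like, cancer-like) sets.
#' @param seed random seed.
#' @return List with `diff`, `hcc` (character vectors) and `truth` (list
#'   with `planted_cluster`, `boost`, `seed`).
#' @export
gen_query_sets <- function(ann, clusters, planted_cluster = NULL, boost = 1,
                           set_sizes = c(481, 143), seed = 1) {
  stopifnot(inherits(ann, "annotation_map"), boost >= 1)
  genes <- names(ann$gene2path)
  if (any(set_sizes > length(genes))) {
    stop("set size exceeds the annotated gene universe")
  }
  w <- rep(1, length(genes))
  if (!is.null(planted_cluster)) {
    stopifnot(inherits(clusters, "cluster_partition"))
    if (!planted_cluster %in% names(clusters$clusters)) {
      stop(sprintf("planted cluster '%s' not in the partition", planted_cluster))
    }
    memb <- clusters$clusters[[planted_cluster]]
    in_planted <- vapply(ann$gene2path, function(p) any(p %in% memb),
                         logical(1))
    w[in_planted] <- boost
  }
  local_seed(seed, {
    list(diff = if (set_sizes[1] > 0) sample(genes, set_sizes[1], prob = w)
         else character(0),
         hcc = if (set_sizes[2] > 0) sample(genes, set_sizes[2], prob = w)
         else character(0),
         truth = list(planted_cluster = planted_cluster, boost = boost,
                      seed = seed))
  })
}

#' Generate a seed-rooted two-layer interactome as PSI-MITAB records
#'
#' Builds a layered interaction network with exact, recorded layer sizes:
#' every layer-1 protein interacts with the seed, every layer-2 protein with
#' at least one layer-1 protein, and extra edges are added within and
#' between the two layers but never incident to the seed, so no shortcut can
#' alter the breadth-first layer assignment. `extra_edge_fraction` is the
#' number of extra edges per base edge (base = layer1 + layer2 attachments);
#' the default reproduces the 17,439-edge scale of a 105/6175-protein
#' neighborhood. Records are emitted as valid MITAB rows tagged with the
#' human taxid; `contaminants` adds rows with a non-matching species for
#' exercising the species filter.
#'
#' @param seed_protein seed identifier, default `"USP15"`.
#' @param layer1_size,layer2_size layer sizes (layer 2 requires a non-empty
#'   layer 1).
#' @param extra_edge_fraction extra edges per base edge, >= 0.
#' @param seed random seed.
#' @param node_pool optional identifier pool to draw protein names from
#'   (e.g. the annotation gene universe); defaults to synthetic accessions.
#' @param include identifiers guaranteed to appear in the layers.
#' @param contaminants number of non-human decoy rows to append.
#' @return List with `records` (character vector of MITAB lines) and
#'   `truth` (list with `layer1`, `layer2`, `n_edges`, `seed`).
#' @export
gen_interactome <- function(seed_protein = "USP15", layer1_size = 105,
                            layer2_size = 6175, extra_edge_fraction = 1.777,
                            seed = 1, node_pool = NULL, include = NULL,
                            contaminants = 0) {
  stopifnot(layer1_size >= 0, layer2_size >= 0, extra_edge_fraction >= 0)
  if (layer2_size > 0 && layer1_size == 0) {
    stop("layer 2 requires a non-empty layer 1")
  }
  local_seed(seed, {
    n_need <- layer1_size + layer2_size
    include <- setdiff(unique(as.character(include %||% character(0))),
                       seed_protein)
    if (length(include) > n_need) stop("more include genes than layer slots")
    if (is.null(node_pool)) {
      node_pool <- sprintf("SYNP%05d", seq_len(n_need * 2L))
    }
    node_pool <- setdiff(unique(as.character(node_pool)),
                         c(seed_protein, include))
    if (length(node_pool) < n_need - length(include)) {
      stop("node pool too small for the requested layer sizes")
    }
    picked <- sample(node_pool, n_need - length(include))
    # forced genes go to layer 2 when it exists, else layer 1
    if (layer2_size >= length(include)) {
      l2 <- c(include, picked[seq_len(layer2_size - length(include))])
      l1 <- picked[(layer2_size - length(include) + 1L):
                     (n_need - length(include))]
      if (layer1_size == 0L) l1 <- character(0)
    } else {
      l1 <- c(include, picked)[seq_len(layer1_size)]
      l2 <- setdiff(c(include, picked), l1)
    }
    l2 <- sample(l2)
    l1 <- if (length(l1)) sample(l1) else l1
    ea <- eb <- character(0)
    if (layer1_size > 0) {
      ea <- rep(seed_protein, layer1_size)
      eb <- l1
    }
    if (layer2_size > 0) {
      ea <- c(ea, l2)
      eb <- c(eb, sample(l1, layer2_size, replace = TRUE))
    }
    n_base <- length(ea)
    n_extra <- round(extra_edge_fraction * n_base)
    if (n_extra > 0) {
      all_nodes <- c(l1, l2)
      seen <- paste(pmin(ea, eb), pmax(ea, eb))
      xa <- xb <- character(0)
      iter <- 0L
      while (length(xa) < n_extra && iter < 1000L) {
        iter <- iter + 1L
        need <- n_extra - length(xa)
        u <- all_nodes[sample.int(length(all_nodes), 2L * need + 10L,
                                  replace = TRUE)]
        v <- all_nodes[sample.int(length(all_nodes), 2L * need + 10L,
                                  replace = TRUE)]
        ok <- u != v
        key <- paste(pmin(u, v), pmax(u, v))
        ok <- ok & !key %in% seen & !duplicated(key)
        u <- u[ok][seq_len(min(need, sum(ok)))]
        v <- v[ok][seq_len(min(need, sum(ok)))]
        xa <- c(xa, u)
        xb <- c(xb, v)
        seen <- c(seen, paste(pmin(u, v), pmax(u, v)))
      }
      ea <- c(ea, xa)
      eb <- c(eb, xb)
    }
    rows <- mitab_lines(ea, eb, taxid = "9606", species = "human")
    if (contaminants > 0) {
      pool2 <- c(l1, l2)
      ca <- pool2[sample.int(length(pool2), contaminants, replace = TRUE)]
      cb <- sprintf("YEAST%03d", seq_len(contaminants))
      rows <- c(rows, mitab_lines(ca, cb, taxid = "559292",
                                  species = "Saccharomyces cerevisiae"))
    }
    list(records = rows,
         truth = list(layer1 = l1, layer2 = l2, n_edges = length(ea),
                      seed = seed))
  })
}

# Format interaction pairs as 15-column PSI-MITAB 2.5 lines.
mitab_lines <- function(a, b, taxid, species) {
  tax <- sprintf("taxid:%s(%s)", taxid, species)
  sprintf(paste0("uniprotkb:%s\tuniprotkb:%s\t-\t-\t-\t-\t",
                 "psi-mi:\"MI:0915\"(physical association)\t-\t-\t",
                 "%s\t%s\t", "psi-mi:\"MI:0915\"(physical association)\t",
                 "psi-mi:\"MI:0469\"(synthetic)\t-\t-"),
          a, b, tax, tax)
}

#' Generate a differential-expression results table with planted hits
#'
#' Planted up-/down-regulated genes receive `|log2FC| >= effect` and
#' `FDR < 0.1`; all other genes receive centered log2FC noise and
#' `FDR >= 0.1`, so the standard filter recovers the planted sets exactly.
#' An effect at or below 1 triggers a warning because planted genes may then
#' fail the fold-change threshold.
#'
#' @param n_genes universe size, default 14099.
#' @param n_up,n_down numbers of planted up- and down-regulated genes.
#' @param effect minimum absolute planted log2 fold-change, > 1.
#' @param seed random seed.
#' @param genes optional gene identifiers (length `n_genes` is then
#'   ignored).
#' @param up_genes,down_genes optional explicit planted gene sets (must be
#'   disjoint subsets of the universe); sizes override `n_up`/`n_down`.
#' @return List with `table` (data frame `gene`, `log2FoldChange`, `padj`)
#'   and `truth` (list with `up`, `down`, `seed`).
#' @export
gen_de_table <- function(n_genes = 14099, n_up = 203, n_down = 278,
                         effect = 2, seed = 1, genes = NULL,
                         up_genes = NULL, down_genes = NULL) {
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(n_genes))
  genes <- unique(as.character(genes))
  n_genes <- length(genes)
  if (effect <= 1) {
    warning("effect <= 1: planted genes may not pass the fold-change filter")
  }
  local_seed(seed, {
    if (is.null(up_genes) || is.null(down_genes)) {
      if (n_up + n_down > n_genes) stop("n_up + n_down exceeds n_genes")
      planted <- sample(genes, n_up + n_down)
      up_genes <- planted[seq_len(n_up)]
      down_genes <- setdiff(planted, up_genes)
    } else {
      up_genes <- unique(as.character(up_genes))
      down_genes <- unique(as.character(down_genes))
      if (length(intersect(up_genes, down_genes)) > 0L) {
        stop("up and down planted sets overlap")
      }
      if (!all(c(up_genes, down_genes) %in% genes)) {
        stop("planted genes outside the gene universe")
      }
    }
    lfc <- stats::rnorm(n_genes, 0, 0.3)
    fdr <- stats::runif(n_genes, 0.1, 1)
    names(lfc) <- names(fdr) <- genes
    lfc[up_genes] <- effect + stats::rexp(length(up_genes), 2)
    lfc[down_genes] <- -(effect + stats::rexp(length(down_genes), 2))
    fdr[c(up_genes, down_genes)] <-
      stats::runif(length(up_genes) + length(down_genes), 0, 0.099)
    list(table = data.frame(gene = genes, log2FoldChange = unname(lfc),
                            padj = unname(fdr), stringsAsFactors = FALSE),
         truth = list(up = up_genes, down = down_genes, seed = seed))
  })
}

#' Generate a cancer-gene mutation-rate table
#'
#' Genes in `cancer_genes` receive cohort mutation rates strictly above 1%,
#' all other genes rates below 1%, so the standard rate filter recovers the
#' planted set exactly.
#'
#' @param genes full gene universe.
#' @param cancer_genes planted high-rate genes (subset of `genes`).
#' @param seed random seed.
#' @return Data frame with columns `gene` and `rate` (percent).
#' @export
gen_cancer_table <- function(genes, cancer_genes, seed = 1) {
  genes <- unique(as.character(genes))
  cancer_genes <- unique(as.character(cancer_genes))
  if (!all(cancer_genes %in% genes)) stop("cancer genes outside the universe")
  local_seed(seed, {
    rate <- stats::runif(length(genes), 0, 0.99)
    names(rate) <- genes
    rate[cancer_genes] <- stats::runif(length(cancer_genes), 1.05, 45)
    data.frame(gene = genes, rate = unname(rate), stringsAsFactors = FALSE)
  })
}

#' Simulate a complete study with planted ground truth
#'
#' Generates every pipeline input — hierarchy, annotations, interactome,
#' differential-expression table, cancer-gene table — from one master seed,
#' with the two evidence sets boosted toward one planted hierarchy cluster.
#' The `"full"` preset mirrors the magnitudes of the motivating study
#' (28-component hierarchy of 2369 nodes, a 14,099-gene universe, a
#' 105/6175-protein two-layer interactome, 203 + 278 planted
#' differential-expression hits, 143 planted cancer-interactome genes); the
#' `"test"` preset is a two-orders-of-magnitude smaller version for fast
#' test suites.
#'
#' @param preset `"test"` or `"full"`.
#' @param seed master seed; stage seeds are derived from it.
#' @param boost planted-cluster sampling boost (>= 1; 1 = null).
#' @param planted_cluster cluster identifier to plant, or `NULL` to pick the
#'   third-largest cluster.
#' @return List with all generated inputs and the combined `truth`.
#' @export
simulate_study <- function(preset = c("test", "full"), seed = 1,
                           boost = 10, planted_cluster = NULL) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  p <- if (preset == "full") {
    list(sizes = reactome_cluster_sizes(), extra_arcs = 29 / 2369,
         universe = 14099L, sampler = NULL,
         set_sizes = c(481L, 143L), n_up = 203L, n_down = 278L,
         l1 = 105L, l2 = 6175L, extra_edges = (17439 - 6280) / 6280,
         extra_cancer = 152L)
  } else {
    list(sizes = c(30L, 25L, 20L, 15L, 12L, 10L, 8L, 4L), extra_arcs = 9 / 124,
         universe = 1500L,
         sampler = function(n) pmax(1L, stats::rpois(n, 6)),
         set_sizes = c(90L, 60L), n_up = 45L, n_down = 45L,
         l1 = 30L, l2 = 220L, extra_edges = 0.5,
         extra_cancer = 20L)
  }
  h <- gen_hierarchy(p$sizes, p$extra_arcs, seed = seed)
  clusters <- suppressWarnings(decompose_clusters(h$network))
  ann <- gen_annotations(h$network, universe_size = p$universe,
                         seed = seed + 1L, count_sampler = p$sampler)
  if (is.null(planted_cluster)) {
    ord <- order(lengths(clusters$clusters), decreasing = TRUE)
    planted_cluster <- names(clusters$clusters)[ord[min(3L, length(ord))]]
  }
  qs <- gen_query_sets(ann, clusters, planted_cluster = planted_cluster,
                       boost = boost, set_sizes = p$set_sizes,
                       seed = seed + 2L)
  universe_genes <- attr(ann, "universe")
  diff_shuffled <- local_seed(seed + 3L, sample(qs$diff))
  up <- diff_shuffled[seq_len(min(p$n_up, length(diff_shuffled)))]
  down <- setdiff(diff_shuffled, up)
  de <- gen_de_table(genes = universe_genes, effect = 2, seed = seed + 4L,
                     up_genes = up, down_genes = down)
  # cancer genes not reachable in the interactome: high mutation rate but
  # excluded from the PPI node pool, as in a real cohort gene list
  extra_cancer <- local_seed(seed + 5L, {
    sample(setdiff(universe_genes, c(qs$diff, qs$hcc)), p$extra_cancer)
  })
  cancer <- gen_cancer_table(universe_genes, c(qs$hcc, extra_cancer),
                             seed = seed + 6L)
  ppi <- gen_interactome(seed_protein = "USP15", layer1_size = p$l1,
                         layer2_size = p$l2,
                         extra_edge_fraction = p$extra_edges,
                         seed = seed + 7L,
                         node_pool = setdiff(universe_genes, extra_cancer),
                         include = qs$hcc)
  list(network = h$network, clusters = clusters, annotations = ann,
       de = de, cancer_table = cancer, interactome = ppi,
       seed_protein = "USP15",
       truth = list(hierarchy = h$truth, query = qs$truth, de = de$truth,
                    cancer = c(qs$hcc, extra_cancer), hcc = qs$hcc,
                    layer1 = ppi$truth$layer1, layer2 = ppi$truth$layer2,
                    planted_cluster = planted_cluster, seed = seed))
}

#' Write ground truth to a JSON file
#'
#' @param truth truth list from a generator.
#' @param file output path.
#' @return The output path, invisibly.
#' @export
write_truth_json <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(file)
}

#' Write MITAB records to a file
#'
#' @param records character vector of MITAB lines (from [gen_interactome()]).
#' @param file output path.
#' @return The output path, invisibly.
#' @export
write_mitab <- function(records, file) {
  writeLines(records, file)
  invisible(file)
}
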