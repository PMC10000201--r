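# End-to-end orchestration: PPI expansion -> cancer-gene intersection ->
# DE filtering -> hierarchy build -> mapping/counting -> scoring ->
# selection -> functional and cluster enrichment.

#' Assemble a pipeline configuration
#'
#' Inputs may be given either as file paths (parsed with the module parsers)
#' or as already-constructed objects, so the pipeline can run on files from
#' disk and on in-memory synthetic data alike. All thresholds default to the
#' standard cut-offs of the analysis: FDR < 0.1, |log2FC| > 1, mutation
#' rate > 1%, score > 20, cluster significance level 0.05.
#'
#' @param relations relation file path or [hierarchy_network()].
#' @param annotations annotation file path or [annotation_map()].
#' @param mitab MITAB file path, character vector of MITAB lines, or a
#'   parsed interaction data frame with columns `a`, `b`.
#' @param de DE table path or data frame (`gene`, `log2fc`, `fdr`).
#' @param cancer cancer-gene table path (TSV with header: gene, rate) or
#'   data frame.
#' @param functional_sets optional named list of pathway-ID vectors.
#' @param seed_protein seed protein identifier, default `"USP15"`.
#' @param species taxid filter for MITAB parsing, default `"9606"`.
#' @param annotation_species species filter for annotation files.
#' @param fdr_max,lfc_min,mutation_min,score_threshold,level thresholds.
#' @param out_dir optional output directory for TSV/SIF exports.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(relations, annotations, mitab, de, cancer,
                            functional_sets = NULL, seed_protein = "USP15",
                            species = "9606",
                            annotation_species = "Homo sapiens",
                            fdr_max = 0.1, lfc_min = 1, mutation_min = 1,
                            score_threshold = 20, level = 0.05,
                            out_dir = NULL) {
  if (fdr_max <= 0 || lfc_min <= 0 || mutation_min < 0 ||
      score_threshold < 0 || level <= 0) {
    stop("invalid thresholds in pipeline configuration")
  }
  structure(list(relations = relations, annotations = annotations,
                 mitab = mitab, de = de, cancer = cancer,
                 functional_sets = functional_sets,
                 seed_protein = seed_protein, species = species,
                 annotation_species = annotation_species,
                 fdr_max = fdr_max, lfc_min = lfc_min,
                 mutation_min = mutation_min,
                 score_threshold = score_threshold, level = level,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative input paths
#' are resolved against the configuration file's directory.
#'
#' @param file YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  base <- dirname(normalizePath(file))
  for (key in c("relations", "annotations", "mitab", "de", "cancer")) {
    v <- cfg[[key]]
    if (is.character(v) && length(v) == 1L && !file.exists(v) &&
        file.exists(file.path(base, v))) {
      cfg[[key]] <- file.path(base, v)
    }
  }
  do.call(pipeline_config, cfg)
}

#' Run the full pipeline
#'
#' Executes the stages in order and returns the complete result bundle.
#' Every stage contributes its input/output cardinalities to the run log;
#' any stage error aborts the run naming the failing stage, and nothing is
#' written to `out_dir` unless all stages succeed (no partial outputs).
#' The pipeline itself is deterministic: identical configuration and inputs
#' give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result` with elements `scores`,
#'   `selection`, `subnetwork`, `functional`, `clusters`, `partition`,
#'   `network`, `ppi`, `de_sets`, `hcc_genes`, `summary`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  logline <- local({
    lines <- character(0)
    function(fmt = NULL, ...) {
      if (is.null(fmt)) return(lines)
      lines <<- c(lines, sprintf(fmt, ...))
      invisible(NULL)
    }
  })
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ppi <- stage("ppi-expansion", {
    rec <- config$mitab
    if (!is.data.frame(rec)) {
      rec <- suppressMessages(parse_mitab(rec, species = config$species))
    }
    layers <- bfs_layers(rec, config$seed_protein, max_depth = 2)
    logline("ppi: %d records, layer 1: %d, layer 2: %d, %d edges",
            nrow(rec), sum(layers$layer == 1L), sum(layers$layer == 2L),
            nrow(layers$edges))
    layers
  })

  hcc_genes <- stage("cancer-gene-intersection", {
    tab <- config$cancer
    if (!is.data.frame(tab)) {
      tab <- utils::read.delim(tab, stringsAsFactors = FALSE)
    }
    mutated <- filter_mutation_rate(tab, config$mutation_min)
    hits <- intersect_network_genes(ppi, mutated)
    logline("cancer genes: %d read, %d with rate > %g%%, %d in the interactome",
            nrow(tab), length(mutated), config$mutation_min, length(hits))
    hits
  })

  de_sets <- stage("de-filtering", {
    de <- config$de
    if (!is.data.frame(de)) de <- read_de_table(de)
    de <- normalize_de_columns(de)
    sets <- filter_de(de, config$fdr_max, config$lfc_min)
    logline("de: %d rows, %d up, %d down", nrow(de), length(sets$up),
            length(sets$down))
    sets
  })

  net <- stage("hierarchy-build", {
    net <- config$relations
    if (!inherits(net, "hierarchy_network")) {
      net <- suppressMessages(parse_relations(net))
    }
    logline("hierarchy: %d nodes, %d arcs, %d sources", length(net$nodes),
            nrow(net$arcs), length(find_source_nodes(net)))
    net
  })

  ann <- stage("annotation-load", {
    ann <- config$annotations
    if (!inherits(ann, "annotation_map")) {
      ann <- suppressMessages(
        read_annotations(ann, species = config$annotation_species))
    }
    logline("annotation: %d genes, %d pathways", length(ann$gene2path),
            length(ann$path2gene))
    ann
  })

  scores <- stage("mapping-and-scoring", {
    diff_genes <- union(de_sets$up, de_sets$down)
    n_tot <- suppressMessages(count_node_genes(net, ann))
    n_diff <- suppressMessages(count_node_genes(net, ann, diff_genes))
    n_hcc <- suppressMessages(count_node_genes(net, ann, hcc_genes))
    tab <- score_all(net, n_tot, n_diff, n_hcc,
                     threshold = config$score_threshold)
    logline("scoring: %d nodes, %d with n_tot > 0, max score %.4g",
            nrow(tab), sum(tab$n_tot > 0), max(tab$s))
    tab
  })

  selection <- stage("selection", {
    sel <- suppressWarnings(suppressMessages(
      select_high_score(scores, config$score_threshold)))
    logline("selection: %d of %d nodes (%.1f%%) with s > %g", length(sel),
            nrow(scores), 100 * length(sel) / max(1L, nrow(scores)),
            config$score_threshold)
    sel
  })

  subnet <- stage("subnetwork", induced_subnetwork(net, selection))

  functional <- stage("functional-enrichment", {
    if (is.null(config$functional_sets) || length(selection) == 0L) {
      NULL
    } else {
      res <- functional_enrichment(selection, config$functional_sets,
                                   net$nodes)
      logline("functional enrichment: %d sets tested", nrow(res))
      res
    }
  })

  partition <- stage("cluster-decomposition",
                     suppressWarnings(decompose_clusters(net)))

  clusters <- stage("cluster-enrichment", {
    res <- cluster_enrichment(selection, partition, net$nodes,
                              level = config$level)
    logline("cluster enrichment: %d of %d clusters enriched at level %g",
            sum(res$enriched), nrow(res), config$level)
    res
  })

  result <- structure(list(
    scores = scores, selection = selection, subnetwork = subnet,
    functional = functional, clusters = clusters, partition = partition,
    network = net, ppi = ppi, de_sets = de_sets, hcc_genes = hcc_genes,
    summary = score_summary(scores), log = logline()
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    stage("export", write_pipeline_outputs(result, config$out_dir))
  }
  result
}

# Write the TSV/SIF/text exports of a finished run.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_score_table(result$scores, file.path(out_dir, "scores.tsv"))
  writeLines(result$selection, file.path(out_dir, "selection.txt"))
  if (!is.null(result$functional)) {
    utils::write.table(result$functional,
                       file.path(out_dir, "functional_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$clusters,
                     file.path(out_dir, "cluster_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sif(result$network, file.path(out_dir, "network.sif"))
  write_sif(result$subnetwork, file.path(out_dir, "subnetwork.sif"))
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  writeLines(report(result), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Human-readable summary of a pipeline run
#'
#' Formats the run the way such analyses are reported: network and layer
#' sizes, evidence-set sizes, the score distribution (over all nodes and
#' over nonzero-scoring nodes), the selection size with its percentage of
#' the universe (one decimal), and per-set / per-cluster enrichment lines
#' with observed and expected overlaps and exact p-values.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @return Character vector of report lines, invisibly; also printed unless
#'   `quiet = TRUE`.
#' @param quiet suppress printing.
#' @export
report <- function(result, quiet = FALSE) {
  stopifnot(inherits(result, "pipeline_result"))
  fmt_p <- function(p) formatC(p, format = "g", digits = 4)
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  net <- result$network
  add("Pathway hierarchy: %d nodes, %d arcs, %d clusters",
      length(net$nodes), nrow(net$arcs), length(result$partition$clusters))
  lt <- table(factor(result$ppi$layer, levels = 0:2))
  add("Interactome of '%s': %d layer-1 and %d layer-2 proteins, %d edges",
      result$ppi$seed, lt[["1"]], lt[["2"]], nrow(result$ppi$edges))
  add("Differentially expressed genes: %d up, %d down",
      length(result$de_sets$up), length(result$de_sets$down))
  add("Cancer genes in the interactome: %d", length(result$hcc_genes))
  s <- result$summary
  add("Score over all nodes: median %.3g, mean %.3g +/- %.3g, max %.3g",
      s$all$median, s$all$mean, s$all$sd, s$all$max)
  add("Score over nonzero nodes: median %.3g, mean %.3g +/- %.3g (n = %d)",
      s$nonzero$median, s$nonzero$mean, s$nonzero$sd, s$nonzero$n)
  add("Selected %d of %d nodes (%.1f%%)", length(result$selection),
      length(net$nodes), 100 * length(result$selection) / length(net$nodes))
  if (length(result$selection) > 0L && !is.null(result$functional)) {
    for (i in seq_len(nrow(result$functional))) {
      r <- result$functional[i, ]
      add("Set '%s': observed %d, expected %.2f, p(enrich) = %s, p(deplete) = %s%s",
          r$label, r$k, r$expected, fmt_p(r$p_upper), fmt_p(r$p_lower),
          if (r$depleted) " [depleted]" else "")
    }
  }
  if (length(result$selection) > 0L) {
    enr <- result$clusters[result$clusters$enriched, , drop = FALSE]
    add("Enriched clusters: %d of %d", nrow(enr), nrow(result$clusters))
    for (i in seq_len(nrow(enr))) {
      r <- enr[i, ]
      add("Cluster '%s': %d of %d selected (%.2f%%), p = %s",
          r$cluster, r$k, r$size, r$percent, fmt_p(r$p_upper))
    }
  } else {
    add("Empty selection: no enrichment computed")
  }
  if (!quiet) cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}

#' @export
print.pipeline_result <- function(x, ...) {
  report(x)
  invisible(x)
}
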