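# Pathway-hierarchy network: construction, sources, clusters, gene counts.

#' Construct a pathway-hierarchy network
#'
#' A hierarchy network is a directed graph in which every node is a pathway
#' (identified by a stable-ID string) and every arc points from a parent
#' pathway to one of its child pathways. The human Reactome hierarchy is the
#' motivating instance: a near-forest of a few thousand nodes in which almost
#' every node has a single parent.
#'
#' @param arcs two-column matrix or data frame of (parent, child) pathway
#'   identifiers; duplicate arcs are collapsed. May have zero rows.
#' @param nodes optional character vector of node identifiers; defaults to the
#'   identifiers appearing in `arcs`. Must contain every arc endpoint.
#' @param names optional named character vector mapping pathway identifiers to
#'   display names.
#' @return An object of class `hierarchy_network`: a list with elements
#'   `nodes` (character), `arcs` (data frame with columns `parent`, `child`)
#'   and `names`.
#' @seealso [parse_relations()], [find_source_nodes()], [decompose_clusters()]
#' @export
hierarchy_network <- function(arcs, nodes = NULL, names = NULL) {
  if (is.null(arcs) || NROW(arcs) == 0L) {
    arcs <- data.frame(parent = character(), child = character(),
                       stringsAsFactors = FALSE)
  } else {
    arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
    if (ncol(arcs) != 2L) stop("arcs must have exactly two columns")
    colnames(arcs) <- c("parent", "child")
    arcs$parent <- as.character(arcs$parent)
    arcs$child <- as.character(arcs$child)
    arcs <- unique(arcs)
    rownames(arcs) <- NULL
  }
  seen <- unique(c(arcs$parent, arcs$child))
  if (is.null(nodes)) {
    nodes <- seen
  } else {
    nodes <- unique(as.character(nodes))
    missing <- setdiff(seen, nodes)
    if (length(missing) > 0L) {
      stop("arc endpoints missing from nodes: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(nodes = nodes, arcs = arcs, names = names),
            class = "hierarchy_network")
}

#' @export
print.hierarchy_network <- function(x, ...) {
  cat(sprintf("Pathway hierarchy network: %d nodes, %d arcs\n",
              length(x$nodes), nrow(x$arcs)))
  invisible(x)
}

#' Parse a pathway-relation file into a hierarchy network
#'
#' Reads a Reactome-style relation file: one `parent<TAB>child` pair of
#' pathway stable IDs per line (any whitespace separates the two columns).
#' Duplicate pairs are collapsed; counts of lines read and arcs kept are
#' reported via [message()].
#'
#' @param file path to a relation file, or a character vector of lines.
#' @return A [hierarchy_network()].
#' @examples
#' net <- parse_relations(c("A\tB", "A\tC", "B\tD"))
#' length(net$nodes)  # 4
#' @export
parse_relations <- function(file) {
  lines <- as_lines(file, "relation input")
  lines <- trimws(lines)
  keep <- nzchar(lines)
  if (!any(keep)) {
    warning("empty relation input: returning an empty network")
    return(hierarchy_network(NULL))
  }
  fields <- strsplit(lines[keep], "[ \t]+")
  nfield <- lengths(fields)
  if (any(nfield != 2L)) {
    bad <- which(keep)[which(nfield != 2L)[1L]]
    stop(sprintf("malformed relation line %d: expected 2 columns, found %d",
                 bad, nfield[which(nfield != 2L)[1L]]))
  }
  m <- matrix(unlist(fields), ncol = 2L, byrow = TRUE)
  net <- hierarchy_network(m)
  message(sprintf("parse_relations: %d lines read, %d distinct arcs, %d nodes",
                  sum(keep), nrow(net$arcs), length(net$nodes)))
  net
}

#' Find source nodes of a hierarchy network
#'
#' A source node is a pathway with in-degree zero, i.e. a top-level pathway
#' that is nobody's child.
#'
#' @param net a [hierarchy_network()].
#' @return Character vector of source-node identifiers.
#' @export
find_source_nodes <- function(net) {
  stopifnot(inherits(net, "hierarchy_network"))
  setdiff(net$nodes, unique(net$arcs$child))
}

#' Decompose a hierarchy network into source-rooted clusters
#'
#' Clusters are the weakly connected components of the network (arc direction
#' ignored). Each cluster is associated with the source node(s) it contains;
#' in a near-forest hierarchy each component carries exactly one source, and
#' the cluster is then named after that source. A component with several
#' sources is kept as one cluster with all its sources listed (with a
#' warning), and a component with no source at all (a pure cycle) is retained
#' with an empty source association and flagged.
#'
#' @param net a [hierarchy_network()].
#' @return An object of class `cluster_partition`: a list with `clusters`
#'   (named list of node-identifier vectors) and `sources` (named list of
#'   source-node vectors, parallel to `clusters`). Cluster sizes always sum
#'   to the number of network nodes.
#' @export
decompose_clusters <- function(net) {
  stopifnot(inherits(net, "hierarchy_network"))
  if (length(net$nodes) == 0L) {
    return(structure(list(clusters = list(), sources = list()),
                     class = "cluster_partition"))
  }
  g <- igraph::graph_from_data_frame(net$arcs, directed = TRUE,
                                     vertices = net$nodes)
  comp <- igraph::components(g, mode = "weak")
  membership <- comp$membership
  sources <- find_source_nodes(net)
  clusters <- split(names(membership), membership)
  src_by_cluster <- lapply(clusters, function(memb) intersect(sources, memb))
  ids <- vapply(seq_along(clusters), function(i) {
    s <- src_by_cluster[[i]]
    if (length(s) == 1L) s else sprintf("component_%d", i)
  }, character(1))
  n_multi <- sum(lengths(src_by_cluster) > 1L)
  if (n_multi > 0L) {
    warning(sprintf("%d cluster(s) contain more than one source node", n_multi))
  }
  n_none <- sum(lengths(src_by_cluster) == 0L)
  if (n_none > 0L) {
    warning(sprintf("%d cluster(s) contain no source node (cycle)", n_none))
  }
  names(clusters) <- ids
  names(src_by_cluster) <- ids
  structure(list(clusters = clusters, sources = src_by_cluster),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("Cluster partition: %d clusters, %d nodes\n",
              length(x$clusters), sum(lengths(x$clusters))))
  invisible(x)
}

#' Count evidence genes per hierarchy node
#'
#' For every node of the network, counts how many of its annotated genes fall
#' in `geneset`. With `geneset = NULL` all annotated genes are counted, which
#' yields the per-node totals used as the denominator of the specificity
#' score. Genes of `geneset` that do not occur anywhere in the annotation map
#' are reported via [message()] and dropped (identifier-namespace mismatches
#' are routine and never a hard error).
#'
#' @param net a [hierarchy_network()].
#' @param ann an [annotation_map()].
#' @param geneset character vector of gene identifiers, or `NULL` for all
#'   annotated genes.
#' @return Named integer vector over all network nodes (unannotated nodes
#'   count 0).
#' @export
count_node_genes <- function(net, ann, geneset = NULL) {
  stopifnot(inherits(net, "hierarchy_network"), inherits(ann, "annotation_map"))
  counts <- stats::setNames(integer(length(net$nodes)), net$nodes)
  annotated <- intersect(net$nodes, names(ann$path2gene))
  if (is.null(geneset)) {
    counts[annotated] <- lengths(ann$path2gene[annotated])
    return(counts)
  }
  geneset <- unique(as.character(geneset))
  unmapped <- setdiff(geneset, names(ann$gene2path))
  if (length(unmapped) > 0L) {
    message(sprintf("count_node_genes: %d of %d genes not in annotation map",
                    length(unmapped), length(geneset)))
  }
  mapped <- setdiff(geneset, unmapped)
  if (length(mapped) > 0L) {
    hits <- table(unlist(ann$gene2path[mapped], use.names = FALSE))
    hits <- hits[names(hits) %in% net$nodes]
    counts[names(hits)] <- as.integer(hits)
  }
  counts
}

#' Summarize per-node gene counts
#'
#' Summary over nodes with at least one mapped gene, matching the reporting
#' convention in which the minimum per-node count is 1 (nodes without any
#' mapped gene are excluded, but their number is available from the input).
#' The dispersion is the population-style standard deviation.
#'
#' @param counts named integer vector as returned by [count_node_genes()].
#' @return List with `min`, `max`, `median`, `mean`, `sd` and `n_nonzero`.
#' @export
summarize_counts <- function(counts) {
  if (length(counts) == 0L) stop("no counts supplied")
  x <- counts[counts >= 1L]
  if (length(x) == 0L) stop("no mapped nodes: all counts are zero")
  list(min = min(x), max = max(x), median = stats::median(x),
       mean = mean(x), sd = sd_pop(x), n_nonzero = length(x))
}

#' Export a hierarchy network
#'
#' `write_sif()` writes the arc list in SIF format
#' (`parent<TAB>relation<TAB>child`), `write_graphml()` in GraphML, both
#' suitable for import into network viewers.
#'
#' @param net a [hierarchy_network()].
#' @param file output path.
#' @param relation relation label for the SIF middle column.
#' @return The output path, invisibly.
#' @export
write_sif <- function(net, file, relation = "parent_of") {
  stopifnot(inherits(net, "hierarchy_network"))
  lines <- character(0)
  if (nrow(net$arcs) > 0L) {
    lines <- sprintf("%s\t%s\t%s", net$arcs$parent, relation, net$arcs$child)
  }
  isolated <- setdiff(net$nodes, c(net$arcs$parent, net$arcs$child))
  lines <- c(lines, isolated)
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_sif
#' @export
write_graphml <- function(net, file) {
  stopifnot(inherits(net, "hierarchy_network"))
  g <- igraph::graph_from_data_frame(net$arcs, directed = TRUE,
                                     vertices = net$nodes)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
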