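# Per-node specificity score and high-score sub-network selection.

#' Specificity score of a pathway node
#'
#' The score combines the three per-node gene counts into
#' \deqn{s = 10^4 \cdot \frac{n_{diff} \, n_{HCC}}{n_{tot}^2},}
#' the product of the node's fraction of differentially expressed genes and
#' its fraction of cancer-interactome genes, scaled by 10^4. A node whose
#' annotated genes are all simultaneously differentially expressed and cancer
#' genes reaches the theoretical upper bound s = 10^4; a node with both
#' fractions at 4.4% scores 19.36, just below the selection threshold of 20.
#' A node without mappable genes (`n_tot = 0`) carries no evidence and scores
#' 0 rather than propagating a division error. The score is dimensionless
#' and invariant under simultaneous scaling of all three counts.
#'
#' @param n_diff,n_hcc,n_tot non-negative counts (vectorized).
#' @return Numeric score in `[0, 1e4]` whenever both gene sets are subsets of
#'   the node's mappable genes.
#' @examples
#' specificity_score(7, 7, 7)        # 10000, the upper bound
#' specificity_score(44, 44, 1000)   # 19.36, below the threshold of 20
#' @export
specificity_score <- function(n_diff, n_hcc, n_tot) {
  if (any(n_diff < 0) || any(n_hcc < 0) || any(n_tot < 0)) {
    stop("counts must be non-negative")
  }
  s <- ifelse(n_tot == 0, 0, 1e4 * n_diff * n_hcc / n_tot^2)
  as.numeric(s)
}

#' Score every node of a hierarchy network
#'
#' Combines the three per-node count maps into a score table. Nodes missing
#' from a count map are treated as count 0.
#'
#' @param net a [hierarchy_network()].
#' @param counts_tot,counts_diff,counts_hcc named integer vectors as from
#'   [count_node_genes()].
#' @param threshold selection threshold applied to fill the `selected`
#'   column, default 20 (strict `s > threshold`).
#' @return Data frame with one row per node and columns `pathway`, `name`
#'   (if the network carries display names), `n_tot`, `n_diff`, `n_hcc`,
#'   `s`, `selected`.
#' @export
score_all <- function(net, counts_tot, counts_diff, counts_hcc,
                      threshold = 20) {
  stopifnot(inherits(net, "hierarchy_network"))
  get0s <- function(cnt) {
    out <- stats::setNames(integer(length(net$nodes)), net$nodes)
    common <- intersect(names(cnt), net$nodes)
    out[common] <- as.integer(cnt[common])
    out
  }
  n_tot <- get0s(counts_tot)
  n_diff <- get0s(counts_diff)
  n_hcc <- get0s(counts_hcc)
  tab <- data.frame(pathway = net$nodes,
                    n_tot = as.integer(n_tot),
                    n_diff = as.integer(n_diff),
                    n_hcc = as.integer(n_hcc),
                    stringsAsFactors = FALSE)
  if (!is.null(net$names)) {
    tab$name <- unname(net$names[tab$pathway])
    tab <- tab[, c("pathway", "name", "n_tot", "n_diff", "n_hcc")]
  }
  tab$s <- specificity_score(tab$n_diff, tab$n_hcc, tab$n_tot)
  tab$selected <- tab$s > threshold
  rownames(tab) <- NULL
  tab
}

#' Summarize the score distribution
#'
#' Reports the distribution of scores both over all nodes and over
#' nonzero-scoring nodes only (the two conventions in which such summaries
#' are commonly stated). Dispersion is the population-style standard
#' deviation.
#'
#' @param table score table from [score_all()].
#' @return List with elements `all` and `nonzero`, each a list of `min`,
#'   `max`, `median`, `mean`, `sd`, `n`.
#' @export
score_summary <- function(table) {
  one <- function(x) {
    if (length(x) == 0L) return(list(min = NA, max = NA, median = NA,
                                     mean = NA, sd = NA, n = 0L))
    list(min = min(x), max = max(x), median = stats::median(x),
         mean = mean(x), sd = sd_pop(x), n = length(x))
  }
  list(all = one(table$s), nonzero = one(table$s[table$s > 0]))
}

#' Select the high-score pathway nodes
#'
#' Selection is strict: `s > threshold`. A score of exactly the threshold is
#' excluded, which keeps the rule deterministic at the boundary. The
#' selected fraction of all nodes is reported via [message()].
#'
#' @param table score table from [score_all()].
#' @param threshold score threshold, default 20.
#' @return Character vector of selected pathway identifiers (possibly empty,
#'   with a warning).
#' @export
select_high_score <- function(table, threshold = 20) {
  stopifnot(threshold >= 0)
  sel <- table$pathway[table$s > threshold]
  if (length(sel) == 0L) {
    warning(sprintf("no nodes with score > %g", threshold))
  } else {
    message(sprintf("selected %d of %d nodes (%.1f%%) with s > %g",
                    length(sel), nrow(table),
                    100 * length(sel) / nrow(table), threshold))
  }
  sel
}

#' Induced sub-network on a node selection
#'
#' Keeps exactly the selected nodes and every original arc whose two
#' endpoints are both selected (the minimal reading of a high-score
#' sub-network: connecting non-selected ancestors are not retained).
#'
#' @param net a [hierarchy_network()].
#' @param selection character vector of node identifiers, subset of
#'   `net$nodes`.
#' @return A [hierarchy_network()] on `selection`.
#' @export
induced_subnetwork <- function(net, selection) {
  stopifnot(inherits(net, "hierarchy_network"))
  selection <- unique(as.character(selection))
  stray <- setdiff(selection, net$nodes)
  if (length(stray) > 0L) {
    stop("selection contains nodes absent from the network: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }
  keep <- net$arcs$parent %in% selection & net$arcs$child %in% selection
  hierarchy_network(net$arcs[keep, , drop = FALSE], nodes = selection,
                    names = net$names)
}

#' Write a score table to TSV
#'
#' @param table score table from [score_all()].
#' @param file output path.
#' @return The output path, invisibly.
#' @export
write_score_table <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
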