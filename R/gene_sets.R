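# Gene evidence sets: differential-expression hits, cancer genes by mutation
# rate, and functional pathway-set definitions.

# Accept both the normalized (gene, log2fc, fdr) layout and tool-native
# column names on in-memory DE tables.
normalize_de_columns <- function(de) {
  stopifnot(is.data.frame(de))
  if (all(c("gene", "log2fc", "fdr") %in% colnames(de))) return(de)
  find <- function(aliases) {
    hit <- match(tolower(aliases), tolower(colnames(de)))
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) {
      stop(sprintf("DE table is missing a column (looked for: %s)",
                   paste(aliases, collapse = ", ")))
    }
    hit[1L]
  }
  out <- data.frame(
    gene = as.character(de[[find(c("gene", "gene_id", "symbol"))]]),
    log2fc = as.numeric(de[[find(c("log2FoldChange", "log2FC", "lfc"))]]),
    fdr = as.numeric(de[[find(c("padj", "FDR", "fdr", "qvalue"))]]),
    stringsAsFactors = FALSE)
  out
}

#' Read a differential-expression results table
#'
#' Reads a tab-separated table with a header, as produced by standard
#' differential-expression tools, and normalizes it to three columns:
#' `gene`, `log2fc`, `fdr`. Column names are matched case-insensitively
#' against configurable alias lists (defaults cover `log2FoldChange` and
#' `padj`). Rows with a missing adjusted p-value are retained with `fdr = NA`;
#' a non-numeric fold-change entry is a row-level parse error.
#'
#' @param file path to a TSV file, or a character vector of lines.
#' @param gene_col,lfc_col,fdr_col candidate column names (first match wins,
#'   case-insensitive).
#' @return Data frame with columns `gene` (character), `log2fc`, `fdr`
#'   (numeric, `fdr` possibly `NA`).
#' @export
read_de_table <- function(file,
                          gene_col = c("gene", "gene_id", "symbol"),
                          lfc_col = c("log2FoldChange", "log2FC", "lfc"),
                          fdr_col = c("padj", "FDR", "fdr", "qvalue")) {
  lines <- as_lines(file, "DE table")
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE, colClasses = "character")
  pick <- function(aliases, what) {
    hit <- match(tolower(aliases), tolower(colnames(tab)))
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) {
      stop(sprintf("DE table is missing a %s column (looked for: %s)",
                   what, paste(aliases, collapse = ", ")))
    }
    colnames(tab)[hit[1L]]
  }
  g <- tab[[pick(gene_col, "gene")]]
  lfc_raw <- tab[[pick(lfc_col, "log2 fold-change")]]
  fdr_raw <- tab[[pick(fdr_col, "FDR")]]
  lfc <- suppressWarnings(as.numeric(lfc_raw))
  bad <- is.na(lfc) & !is.na(lfc_raw) & !(trimws(lfc_raw) %in% c("", "NA"))
  if (any(bad)) {
    stop(sprintf("non-numeric log2 fold-change in DE table row %d: '%s'",
                 which(bad)[1L], lfc_raw[which(bad)[1L]]))
  }
  fdr <- suppressWarnings(as.numeric(fdr_raw))
  if (any(!is.na(fdr) & (fdr < 0 | fdr > 1))) {
    stop("FDR values outside [0, 1] in DE table")
  }
  data.frame(gene = as.character(g), log2fc = lfc, fdr = fdr,
             stringsAsFactors = FALSE)
}

#' Filter differential-expression records into up- and down-regulated sets
#'
#' Applies the strict thresholds `fdr < fdr_max` and `|log2fc| > lfc_min`
#' (boundary values excluded on both). Rows with a missing FDR are treated as
#' not significant and excluded from both sets; the up and down sets are
#' disjoint by construction.
#'
#' @param de data frame as returned by [read_de_table()].
#' @param fdr_max FDR cut-off, default 0.1.
#' @param lfc_min absolute log2 fold-change cut-off, default 1.
#' @return List with character vectors `up` and `down`.
#' @export
filter_de <- function(de, fdr_max = 0.1, lfc_min = 1) {
  stopifnot(fdr_max > 0, lfc_min > 0)
  de <- normalize_de_columns(de)
  sig <- !is.na(de$fdr) & de$fdr < fdr_max
  list(up = unique(de$gene[sig & de$log2fc > lfc_min]),
       down = unique(de$gene[sig & de$log2fc < -lfc_min]))
}

#' Select cancer genes by cohort mutation rate
#'
#' Keeps genes whose mutation rate (percent of the cohort) strictly exceeds
#' `min_rate`; the boundary value is excluded.
#'
#' @param records data frame with columns `gene` and `rate` (percent, >= 0).
#' @param min_rate threshold in percent, default 1.
#' @return Character vector of gene identifiers.
#' @export
filter_mutation_rate <- function(records, min_rate = 1) {
  stopifnot(min_rate >= 0)
  if (NROW(records) == 0L) return(character(0))
  out <- unique(as.character(records$gene[records$rate > min_rate]))
  if (length(out) == 0L) {
    warning(sprintf("no genes with mutation rate > %g%%", min_rate))
  }
  out
}

#' Read functional pathway-set definitions
#'
#' Each input is a plain-text file (or character vector) listing one pathway
#' identifier per line; duplicates are removed. When a hierarchy network is
#' supplied, members absent from it are dropped and their count reported,
#' since enrichment is only defined over the hierarchy's node universe.
#'
#' @param files list (or vector) of file paths or character vectors, one per
#'   set.
#' @param labels set labels (e.g. `"cell proliferation"`), parallel to
#'   `files`.
#' @param net optional [hierarchy_network()] to intersect against.
#' @return Named list of character vectors; sets may overlap and may be
#'   empty (with a warning) after intersection.
#' @export
read_functional_sets <- function(files, labels, net = NULL) {
  stopifnot(length(files) == length(labels))
  out <- vector("list", length(files))
  names(out) <- labels
  for (i in seq_along(files)) {
    ids <- unique(trimws(as_lines(files[[i]], "functional set")))
    ids <- ids[nzchar(ids)]
    if (!is.null(net)) {
      dropped <- setdiff(ids, net$nodes)
      if (length(dropped) > 0L) {
        message(sprintf("functional set '%s': %d of %d members not in hierarchy, dropped",
                        labels[[i]], length(dropped), length(ids)))
      }
      ids <- intersect(ids, net$nodes)
      if (length(ids) == 0L) {
        warning(sprintf("functional set '%s' is empty after intersection with the hierarchy",
                        labels[[i]]))
      }
    }
    out[[i]] <- ids
  }
  out
}
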