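# Gene-to-pathway annotation maps (UniProt2Reactome-style input).

#' Construct a gene-to-pathway annotation map
#'
#' Stores the many-to-many mapping between genes and pathway nodes in both
#' directions. The two views are exact inverses by construction; empty gene
#' entries are impossible because the map is keyed on observed
#' (gene, pathway) pairs.
#'
#' @param gene character vector of gene identifiers.
#' @param pathway character vector of pathway identifiers, parallel to `gene`.
#' @param namespace identifier namespace tag (e.g. `"uniprot"` for
#'   accession-style or `"symbol"` for gene-symbol identifiers); purely
#'   descriptive.
#' @return An object of class `annotation_map`: list with `gene2path` and
#'   `path2gene` (named lists of character vectors) and `namespace`.
#' @export
annotation_map <- function(gene, pathway, namespace = "uniprot") {
  stopifnot(length(gene) == length(pathway))
  gene <- as.character(gene)
  pathway <- as.character(pathway)
  keep <- nzchar(gene) & nzchar(pathway)
  pairs <- unique(data.frame(gene = gene[keep], pathway = pathway[keep],
                             stringsAsFactors = FALSE))
  structure(list(
    gene2path = split(pairs$pathway, pairs$gene),
    path2gene = split(pairs$gene, pairs$pathway),
    namespace = namespace
  ), class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("Annotation map (%s): %d genes, %d pathways\n",
              x$namespace, length(x$gene2path), length(x$path2gene)))
  invisible(x)
}

#' Read a UniProt2Reactome-style annotation file, filtered to one species
#'
#' Expects the six-column tab-separated layout of Reactome's
#' `UniProt2Reactome` exports: accession, pathway stable-ID, URL, pathway
#' name, evidence code, species. Only rows whose species column matches
#' `species` exactly (after trimming) are kept; evidence codes and URLs are
#' ignored, and duplicate (gene, pathway) pairs are collapsed. Rows missing
#' the species field are skipped with a warning.
#'
#' @param file path to the annotation file, or a character vector of lines.
#' @param species species to retain, default `"Homo sapiens"`.
#' @param namespace namespace tag recorded on the map.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(file, species = "Homo sapiens",
                             namespace = "uniprot") {
  lines <- as_lines(file, "annotation input")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty annotation input")
    return(annotation_map(character(0), character(0), namespace))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  short <- nfield < 6L
  if (any(short)) {
    warning(sprintf("%d annotation row(s) without a species field skipped",
                    sum(short)))
    fields <- fields[!short]
  }
  if (length(fields) == 0L) {
    warning("no annotation rows left after filtering")
    return(annotation_map(character(0), character(0), namespace))
  }
  acc <- vapply(fields, `[[`, character(1), 1L)
  path <- vapply(fields, `[[`, character(1), 2L)
  sp <- trimws(vapply(fields, `[[`, character(1), 6L))
  keep <- sp == species
  if (!any(keep)) {
    warning(sprintf("no annotation rows match species '%s'", species))
  }
  message(sprintf("read_annotations: %d rows read, %d rows for '%s'",
                  length(fields), sum(keep), species))
  annotation_map(acc[keep], path[keep], namespace)
}
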