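# Seed-centered layered protein-protein interaction network.
#
# Layer 1 holds the direct interaction partners of the seed protein, layer 2
# the partners of layer-1 proteins; layers are shortest-path distances, so a
# protein reachable at distance 1 is never demoted to layer 2 by a longer
# route.

#' Parse PSI-MITAB interaction records
#'
#' Reads PSI-MITAB 2.5/2.7 tab-separated rows and returns deduplicated,
#' unordered interaction pairs. The identifier of each interactor is chosen
#' by preference: the first `uniprotkb:` accession in the primary-identifier
#' column, otherwise the first `db:accession` value. Rows are kept only when
#' both interactors match the species filter (taxid or species-name match on
#' columns 10 and 11). When the MITAB 2.7 interactor-type columns (21, 22)
#' are present, rows whose type mentions a small molecule are dropped, which
#' removes compounds from the network. Self-interactions are retained but
#' flagged. Comment/header lines starting with `#` are skipped, and rows
#' whose identifier columns cannot be parsed are counted and skipped.
#'
#' @param file path to a MITAB file, or a character vector of lines.
#' @param species taxid (e.g. `"9606"`) or species name fragment to require
#'   on both interactors.
#' @return Data frame with columns `a`, `b` (character identifiers, pair
#'   sorted so that duplicates collapse) and `self` (logical).
#' @export
parse_mitab <- function(file, species = "9606") {
  lines <- as_lines(file, "MITAB input")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(a = character(), b = character(), self = logical(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  usable <- nfield >= 11L
  if (any(!usable)) {
    message(sprintf("parse_mitab: %d row(s) with too few columns skipped",
                    sum(!usable)))
    fields <- fields[usable]
  }
  if (length(fields) == 0L) {
    return(data.frame(a = character(), b = character(), self = logical(),
                      stringsAsFactors = FALSE))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  pick_id <- function(x) {
    out <- character(length(x))
    has <- grepl("uniprotkb:", x, fixed = TRUE)
    out[has] <- sub("^uniprotkb:", "", vapply(which(has), function(i) {
      regmatches(x[i], regexpr("uniprotkb:[^|()\t]+", x[i]))
    }, character(1)))
    rest <- !has & grepl(":", x, fixed = TRUE)
    out[rest] <- sub("^[^:]+:", "", sub("\\|.*$", "", x[rest]))
    out
  }
  ida <- pick_id(col(1L))
  idb <- pick_id(col(2L))
  sp_pat <- if (grepl("^[0-9]+$", species)) {
    paste0("taxid:", species, "(\\(|\\||$)")
  } else {
    species
  }
  sp_ok <- grepl(sp_pat, col(10L)) & grepl(sp_pat, col(11L))
  type_ok <- rep(TRUE, length(fields))
  has_type <- nfield[usable] >= 22L
  if (any(has_type)) {
    t21 <- vapply(fields, function(f) if (length(f) >= 21L) f[[21L]] else "", character(1))
    t22 <- vapply(fields, function(f) if (length(f) >= 22L) f[[22L]] else "", character(1))
    type_ok <- !grepl("small molecule", t21, ignore.case = TRUE) &
      !grepl("small molecule", t22, ignore.case = TRUE)
  }
  parse_ok <- nzchar(ida) & nzchar(idb)
  if (any(!parse_ok)) {
    message(sprintf("parse_mitab: %d row(s) with unparseable identifiers skipped",
                    sum(!parse_ok)))
  }
  keep <- parse_ok & sp_ok & type_ok
  a <- ida[keep]
  b <- idb[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  rec <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  rec$self <- rec$a == rec$b
  message(sprintf("parse_mitab: %d rows read, %d records kept (%d self-loops)",
                  length(fields), nrow(rec), sum(rec$self)))
  rec
}

#' Expand the layered interaction neighborhood of a seed protein
#'
#' Breadth-first expansion from the seed: layer of a protein is its
#' unweighted shortest-path distance from the seed, so the seed is layer 0,
#' its direct partners layer 1, and proteins first reachable through a
#' layer-1 protein are layer 2. Nodes beyond `max_depth` are excluded.
#' Self-loops are never traversed (a self-interaction cannot create a new
#' layer) and are omitted from the retained edge set; all other edges among
#' retained nodes are kept, including edges within a layer, which do not
#' affect layer assignment.
#'
#' @param records interaction data frame with columns `a` and `b`, as from
#'   [parse_mitab()].
#' @param seed seed protein identifier; must occur in `records`.
#' @param max_depth number of layers to expand, default 2.
#' @return Object of class `ppi_layers`: list with `seed`, `layer` (named
#'   integer vector, seed included at 0) and `edges` (data frame `a`, `b`).
#' @export
bfs_layers <- function(records, seed, max_depth = 2) {
  stopifnot(NROW(records) >= 1L, max_depth >= 0)
  a <- as.character(records$a)
  b <- as.character(records$b)
  if (!(seed %in% c(a, b))) stop(sprintf("seed '%s' not found in records", seed))
  keep <- a != b
  adj <- split(c(b[keep], a[keep]), c(a[keep], b[keep]))
  layer <- stats::setNames(0L, seed)
  frontier <- seed
  depth <- 0L
  while (length(frontier) > 0L && depth < max_depth) {
    depth <- depth + 1L
    nbr <- unique(unlist(adj[frontier], use.names = FALSE))
    nbr <- setdiff(nbr, names(layer))
    if (length(nbr) == 0L) break
    layer[nbr] <- depth
    frontier <- nbr
  }
  nodes <- names(layer)
  e_keep <- keep & a %in% nodes & b %in% nodes
  edges <- unique(data.frame(a = pmin(a[e_keep], b[e_keep]),
                             b = pmax(a[e_keep], b[e_keep]),
                             stringsAsFactors = FALSE))
  structure(list(seed = seed, layer = layer, edges = edges),
            class = "ppi_layers")
}

#' @export
print.ppi_layers <- function(x, ...) {
  tab <- table(x$layer)
  cat(sprintf("Layered PPI network around '%s': %s; %d edges\n", x$seed,
              paste(sprintf("layer %s: %d", names(tab), as.integer(tab)),
                    collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Intersect a gene set with the interaction neighborhood
#'
#' Returns the genes that are layer-1 or layer-2 members of the layered
#' network (the seed itself is excluded). Matching is symbol-level and
#' case-insensitive; the returned identifiers keep the caller's spelling.
#'
#' @param net a `ppi_layers` object from [bfs_layers()].
#' @param genes character vector of gene identifiers.
#' @return Character vector, subset of `genes`.
#' @export
intersect_network_genes <- function(net, genes) {
  stopifnot(inherits(net, "ppi_layers"))
  members <- names(net$layer)[net$layer > 0L]
  genes <- unique(as.character(genes))
  genes[toupper(genes) %in% toupper(members)]
}

#' Mediator sub-network between a seed protein and target proteins
#'
#' Builds the sub-network containing the seed, each target, and every
#' interaction partner of the seed or of any target; its edges are all input
#' interactions among these nodes. Each target is annotated with whether it
#' interacts at all, whether it binds the seed directly, and whether it is
#' connected to the seed through at most one mediator protein. Targets
#' without any recorded interaction are retained as isolated nodes and
#' flagged.
#'
#' @param records interaction data frame with columns `a`, `b`.
#' @param seed seed protein identifier.
#' @param targets non-empty character vector of target identifiers.
#' @return List with `nodes`, `edges`, and `targets` (data frame with columns
#'   `target`, `in_network`, `direct`, `mediated`).
#' @export
target_subnetwork <- function(records, seed, targets) {
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) stop("targets must be non-empty")
  a <- as.character(records$a)
  b <- as.character(records$b)
  partners <- function(x) {
    unique(c(b[a == x], a[b == x]))
  }
  anchor <- c(seed, targets)
  nodes <- unique(c(anchor, unlist(lapply(anchor, partners), use.names = FALSE)))
  e_keep <- a %in% nodes & b %in% nodes
  edges <- unique(data.frame(a = pmin(a[e_keep], b[e_keep]),
                             b = pmax(a[e_keep], b[e_keep]),
                             stringsAsFactors = FALSE))
  seed_nbr <- setdiff(partners(seed), seed)
  tinfo <- data.frame(target = targets, stringsAsFactors = FALSE)
  tinfo$in_network <- vapply(targets, function(t) length(partners(t)) > 0L,
                             logical(1))
  tinfo$direct <- targets %in% seed_nbr
  tinfo$mediated <- vapply(targets, function(t) {
    length(intersect(setdiff(partners(t), c(seed, t)), seed_nbr)) > 0L
  }, logical(1)) | tinfo$direct
  iso <- tinfo$target[!tinfo$in_network]
  if (length(iso) > 0L) {
    message(sprintf("target_subnetwork: %d target(s) without interactions: %s",
                    length(iso), paste(iso, collapse = ", ")))
  }
  list(nodes = nodes, edges = edges, targets = tinfo)
}
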