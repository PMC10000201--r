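# Hypergeometric enrichment and depletion of pathway sets and clusters
# within a high-score selection.
#
# The model: a selection of n pathways drawn from a universe of N, a
# category of K pathways, and the observed overlap k, tested against
# X ~ Hypergeometric(N, K, n) with exact tail sums (no normal
# approximation).

#' Expected overlap under random selection
#'
#' The mean overlap between a random selection of `n` pathways and a
#' category of `K` pathways in a universe of `N` is `K * n / N`.
#'
#' @param K category size.
#' @param n selection size.
#' @param N universe size (>= 1).
#' @return The expected overlap, a real number.
#' @examples
#' expected_count(163, 225, 2423)  # about 15.14
#' @export
expected_count <- function(K, n, N) {
  if (N < 1) stop("universe size N must be >= 1")
  stopifnot(K >= 0, n >= 0, K <= N, n <= N)
  K * n / N
}

#' Exact hypergeometric tail probability
#'
#' Tail probability of the overlap `k` under X ~ Hypergeometric(N, K, n).
#' With `inclusive = TRUE` (the default and the proper p-value convention)
#' the upper tail is P(X >= k) and the lower tail P(X <= k). With
#' `inclusive = FALSE` the observed value is excluded from the tail:
#' the upper tail becomes P(X > k) = 1 - CDF(k), the convention obtained
#' when a spreadsheet's cumulative distribution is subtracted from one,
#' and the lower tail P(X < k). Both conventions are exact tail sums.
#'
#' @param N universe size.
#' @param K number of category members in the universe.
#' @param n number of draws (selection size).
#' @param k observed overlap; must satisfy `0 <= k <= min(K, n)`.
#' @param tail `"upper"` for enrichment, `"lower"` for depletion.
#' @param inclusive whether the tail includes the observed value.
#' @return A probability in `[0, 1]`.
#' @examples
#' hypergeom_pvalue(2423, 143, 225, 7, tail = "lower")  # about 0.0354
#' @export
hypergeom_pvalue <- function(N, K, n, k, tail = c("upper", "lower"),
                             inclusive = TRUE) {
  tail <- match.arg(tail)
  stopifnot(N >= 0, K >= 0, n >= 0, K <= N, n <= N)
  if (k < 0 || k > K || k > n) {
    stop(sprintf("inconsistent parameters: k = %g must lie in [0, min(K = %g, n = %g)]",
                 k, K, n))
  }
  p <- if (tail == "upper") {
    q <- if (inclusive) k - 1 else k
    stats::phyper(q, K, N - K, n, lower.tail = FALSE)
  } else {
    q <- if (inclusive) k else k - 1
    stats::phyper(q, K, N - K, n, lower.tail = TRUE)
  }
  min(max(p, 0), 1)
}

#' Enrichment and depletion of functional pathway sets in a selection
#'
#' For each functional set, members are first intersected with the universe
#' (K is the in-universe category size), the overlap with the selection is
#' counted, and both exact tails are computed. A set whose observed overlap
#' falls below its expectation is flagged as depleted; both tails are always
#' retained in the result so either direction can be reported.
#'
#' @param selection character vector of selected pathway identifiers
#'   (subset of `universe`).
#' @param sets named list of character vectors (e.g. from
#'   [read_functional_sets()]).
#' @param universe character vector of all pathway identifiers (the
#'   hierarchy's node set).
#' @return Data frame with columns `label`, `N`, `K`, `n`, `k`, `expected`,
#'   `p_upper`, `p_lower`, `depleted`.
#' @export
functional_enrichment <- function(selection, sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  selection <- unique(as.character(selection))
  stray <- setdiff(selection, universe)
  if (length(stray) > 0L) {
    stop("selection contains identifiers outside the universe")
  }
  N <- length(universe)
  n <- length(selection)
  rows <- lapply(names(sets), function(lab) {
    members <- intersect(unique(as.character(sets[[lab]])), universe)
    K <- length(members)
    k <- length(intersect(selection, members))
    data.frame(label = lab, N = N, K = K, n = n, k = k,
               expected = expected_count(K, n, N),
               p_upper = hypergeom_pvalue(N, K, n, k, "upper"),
               p_lower = hypergeom_pvalue(N, K, n, k, "lower"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$depleted <- out$k < out$expected
  out
}

#' Enrichment of hierarchy clusters in a selection
#'
#' Tests each cluster of the hierarchy partition for over-representation of
#' the selected pathways: K is the cluster size, k the number of selected
#' pathways in the cluster, and the upper-tail hypergeometric p-value is
#' computed exactly. Because the clusters partition the universe, the
#' per-cluster overlaps always sum to the selection size.
#'
#' @param selection character vector of selected pathway identifiers.
#' @param clusters a `cluster_partition` from [decompose_clusters()].
#' @param universe character vector of all pathway identifiers; the clusters
#'   must partition it.
#' @param level significance level for the `enriched` flag, default 0.05.
#' @param inclusive tail convention passed to [hypergeom_pvalue()].
#' @return Data frame with columns `cluster`, `size`, `k`, `percent`
#'   (100 k / K), `expected`, `p_upper`, `enriched`.
#' @export
cluster_enrichment <- function(selection, clusters, universe, level = 0.05,
                               inclusive = TRUE) {
  stopifnot(inherits(clusters, "cluster_partition"))
  universe <- unique(as.character(universe))
  memb <- unlist(clusters$clusters, use.names = FALSE)
  if (length(memb) != length(universe) || !setequal(memb, universe)) {
    stop("clusters do not partition the universe")
  }
  selection <- unique(as.character(selection))
  N <- length(universe)
  n <- length(selection)
  rows <- lapply(names(clusters$clusters), function(id) {
    memb <- clusters$clusters[[id]]
    K <- length(memb)
    k <- length(intersect(selection, memb))
    data.frame(cluster = id, size = K, k = k,
               percent = 100 * k / K,
               expected = expected_count(K, n, N),
               p_upper = hypergeom_pvalue(N, K, n, k, "upper",
                                          inclusive = inclusive),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$enriched <- out$p_upper < level
  out
}

#' Benjamini-Hochberg adjustment of enrichment results
#'
#' Optional multiple-testing correction across the rows of an enrichment
#' result table (raw p-values are reported by default, matching the practice
#' of reporting a handful of planned tests uncorrected).
#'
#' @param result data frame with a `p_upper` column.
#' @return The input with an added `p_upper_bh` column.
#' @export
adjust_enrichment <- function(result) {
  result$p_upper_bh <- stats::p.adjust(result$p_upper, method = "BH")
  result
}
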