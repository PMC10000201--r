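# Independent oracles and small fixture builders shared across tests.

# Exhaustive hypergeometric tail by direct combinatorial summation:
# P(X >= k) (or <= k) for X ~ Hypergeometric(N, K, n), from choose() only.
hyper_tail_oracle <- function(N, K, n, k, tail = "upper", inclusive = TRUE) {
  lo <- max(0L, n - (N - K))
  hi <- min(K, n)
  support <- lo:hi
  mass <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  keep <- if (tail == "upper") {
    if (inclusive) support >= k else support > k
  } else {
    if (inclusive) support <= k else support < k
  }
  sum(mass[keep])
}

# Two-tailed Fisher p by brute force over every table with the observed
# margins, using only choose().
fisher_oracle <- function(t) {
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ])
  c1 <- sum(t[, 1]); N <- sum(t)
  x <- max(0L, c1 - r2):min(r1, c1)
  prob <- choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  p_obs <- prob[x == t[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# A small fixed hierarchy: two components (a 5-node tree and a 3-node chain).
tiny_hierarchy <- function() {
  hierarchy_network(rbind(
    c("A", "B"), c("A", "C"), c("B", "D"), c("B", "E"),
    c("X", "Y"), c("Y", "Z")
  ))
}

# A small annotation map over the tiny hierarchy.
tiny_annotation <- function() {
  annotation_map(
    gene = c("g1", "g2", "g3", "g1", "g4", "g5", "g5", "g6"),
    pathway = c("A", "A", "A", "B", "B", "X", "Y", "Z")
  )
}
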