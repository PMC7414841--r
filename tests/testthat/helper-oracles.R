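# Fixture builders and independent oracles used across the suite.
# Oracles deliberately avoid the code paths they check: shortest paths by
# Floyd-Warshall on the adjacency matrix, tail probabilities by explicit
# binomial-coefficient sums, component structure by matrix reachability.

suppressPackageStartupMessages(library(igraph))

# Erdos-Renyi test graph with named vertices.
randomTestGraph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  g
}

# All-pairs shortest path lengths via Floyd-Warshall (independent of
# igraph's BFS).
fwDistances <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# Brute-force closest distance d_c with the same disconnected-target
# exclusion rule.
oracleClosestDistance <- function(g, S, T) {
  D <- fwDistances(g)
  S <- intersect(S, rownames(D)); T <- intersect(T, rownames(D))
  nearest <- apply(D[T, S, drop = FALSE], 1, min)
  nearest <- nearest[is.finite(nearest)]
  list(d_c = mean(nearest), n = length(nearest))
}

# Hypergeometric upper tail by explicit coefficient sum.
oracleHyperTail <- function(N, s0, k, ks) {
  if (ks <= 0) return(1)
  i <- ks:min(k, s0)
  sum(choose(s0, i) * choose(N - s0, k - i)) / choose(N, k)
}

# Exhaustive enumeration of all C(N, k) neighbour configurations.
oracleHyperEnum <- function(N, s0, k, ks) {
  hits <- 0
  cfg <- utils::combn(N, k)
  for (j in seq_len(ncol(cfg))) {
    if (sum(cfg[, j] <= s0) >= ks) hits <- hits + 1
  }
  hits / ncol(cfg)
}

# One-sided binomial tail by explicit sum.
oracleBinomTail <- function(h, n, p) {
  if (h <= 0) return(1)
  i <- h:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# Assert that at every iteration of a DIAMOnD ranking the chosen gene
# minimized the connectivity p-value, by recomputing p for all
# module-adjacent candidates from scratch.
checkDiamondMinimality <- function(g, seeds, ranking) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  nodes <- rownames(A)
  N <- length(nodes)
  module <- intersect(seeds, nodes)
  for (i in seq_len(nrow(ranking))) {
    ks <- colSums(A[module, , drop = FALSE])
    cand <- setdiff(nodes[ks > 0], module)
    p <- vapply(cand, function(v)
      oracleHyperTail(N, length(module), sum(A[v, ]), ks[v]), numeric(1))
    chosen <- ranking$gene[i]
    if (p[chosen] > min(p) + 1e-12) return(FALSE)
    if (abs(p[chosen] - ranking$p_conn[i]) > 1e-9) return(FALSE)
    module <- c(module, chosen)
  }
  TRUE
}

# Write a tiny edge-list fixture and return its path.
edgeFileFixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

pathGraph5 <- function() igraph::make_graph(~ A - B - C - D - E)
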