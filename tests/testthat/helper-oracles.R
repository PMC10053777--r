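# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: explicit combinatorial sums instead of phyper,
# union-find instead of igraph, direct set arithmetic instead of the
# package's set operations.

# Upper-tail hypergeometric P(X >= k) by explicit combinatorial summation.
hyperEnumOracle <- function(N, K, n, k) {
  i <- seq(max(0, k), min(K, n))
  if (!length(i)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Connected components of an undirected edge list by union-find.
unionFindComponents <- function(nodes, edgesFrom, edgesTo) {
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (e in seq_along(edgesFrom)) {
    ri <- find(match(edgesFrom[e], nodes))
    rj <- find(match(edgesTo[e], nodes))
    if (ri != rj) parent[[ri]] <- rj
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  setNames(match(roots, unique(roots)), nodes)
}

# Same partition up to label permutation?
samePartition <- function(a, b) {
  stopifnot(length(a) == length(b))
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# A tiny contrast table for threshold tests.
toyContrast <- function(lfc, padj, p = padj) {
  data.frame(gene_id = sprintf("g%03d", seq_along(lfc)),
             log2FC = lfc, wald_stat = NA_real_, p = p, p_adj = padj)
}

# Deterministic random gene-set pair for set-statistic fuzzing.
randomSetPair <- function(universeSize = 60) {
  u <- sprintf("x%03d", seq_len(universeSize))
  a <- sample(u, sample(1:universeSize, 1))
  b <- sample(u, sample(1:universeSize, 1))
  list(a = a, b = b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bare-hands GeneSetCollection builder for toy fixtures.
makeCollection <- function(ids, sets, ns = NULL) {
  new("GeneSetCollection", termId = ids,
      termName = paste("term", ids),
      namespace = ns %||% rep("BP", length(ids)),
      genes = sets, universe = character())
}
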