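# Independent oracles used by the unit and acceptance tests. These are
# deliberately brute-force re-derivations, sharing no code with the
# package implementations they check.

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n, n1) assignments of the pooled ranks to the first group.
# Valid with ties (midranks). The two-sided p is the permutation mass
# at least as far from the permutation mean as the observed statistic.
oracle_rank_sum_exact <- function(x, in_group) {
  n <- length(x)
  n1 <- sum(in_group)
  r <- rank(x)
  combs <- utils::combn(n, n1)
  W <- colSums(matrix(r[combs], nrow = n1))
  w_obs <- sum(r[in_group])
  mu <- mean(W)
  mean(abs(W - mu) >= abs(w_obs - mu) - 1e-9)
}

# Naive agglomerative clustering: clusters start as singletons; at each
# step the pair with the smallest inter-cluster distance merges, where
# the inter-cluster distance is recomputed from the original pairwise
# distances (mean over all cross pairs for average linkage, max for
# complete). Returns the merge heights and the member sets merged.
oracle_agglomerate <- function(d, linkage = "average") {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        cross <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        dist_ij <- if (linkage == "average") mean(cross) else max(cross)
        if (is.null(best) || dist_ij < best$d) {
          best <- list(i = i, j = j, d = dist_ij)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- merged
    heights <- c(heights, best$d)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(merges = merges, heights = heights)
}

# Arithmetic per-cluster mean of a genes x cells matrix, computed the
# slow way (per-gene, per-cluster loops).
oracle_cluster_means <- function(x, labels) {
  x <- as.matrix(x)
  clusters <- sort(unique(labels))
  out <- matrix(NA_real_, nrow(x), length(clusters),
                dimnames = list(rownames(x), clusters))
  for (cl in clusters) {
    cols <- which(labels == cl)
    for (g in seq_len(nrow(x))) out[g, cl] <- mean(x[g, cols])
  }
  out
}
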