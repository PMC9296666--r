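# Wilcoxon rank-sum machinery.
#
# Two routes to a two-sided p-value for the rank-sum statistic W (sum of
# midranks in the first group):
#   * exact: the permutation distribution of W over all subsets of the
#     pooled ranks, counted by dynamic programming over doubled midranks
#     (doubling makes tied midranks integral). Handles ties exactly.
#   * normal: tie-corrected normal approximation with continuity
#     correction, the standard large-sample route.
# Both define the two-sided p as the probability mass at least as far
# from the permutation mean as the observed W.

rank_sum_exact_p <- function(r, n1) {
  n <- length(r)
  d <- as.integer(round(2 * r))          # doubled midranks are integers
  w_obs <- sum(d[seq_len(n1)])
  mu <- n1 * (n + 1)                     # mean of doubled rank sum
  total <- sum(d)
  # f[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(n)) {
    kmax <- min(i, n1)
    for (k in kmax:1) {
      src <- f[k, ]
      nz <- which(src != 0)
      if (length(nz) > 0) {
        idx <- nz + d[i]
        f[k + 1L, idx] <- f[k + 1L, idx] + src[nz]
      }
    }
  }
  counts <- f[n1 + 1L, ]
  sums <- seq_along(counts) - 1L
  dev_obs <- abs(w_obs - mu)
  extreme <- abs(sums - mu) >= dev_obs - 1e-9
  sum(counts[extreme]) / sum(counts)
}

rank_sum_normal_p <- function(r, n1) {
  n <- length(r)
  n2 <- n - n1
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)   # continuity corrected
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Tests whether values in one group are stochastically larger or
#' smaller than in the other. With `exact = "auto"` the full permutation
#' distribution of the rank sum is enumerated (by dynamic programming
#' over tied midranks) whenever the pooled size is at most
#' `exact_max_n`; larger instances use the tie-corrected normal
#' approximation with continuity correction. The exact route is valid
#' with ties, unlike the classical no-tie exact distribution.
#'
#' @param x Numeric values.
#' @param in_group Logical vector: `TRUE` for the first group.
#' @param exact `"auto"`, `"always"` or `"never"`.
#' @param exact_max_n Pooled-size bound for the automatic exact route.
#' @return List with `statistic` (rank sum of the first group),
#'   `p_value` and `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, in_group, exact = c("auto", "always", "never"),
                          exact_max_n = 30L) {
  exact <- match.arg(exact)
  in_group <- as.logical(in_group)
  stopifnot(length(x) == length(in_group))
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(x)
  r_ord <- c(r[in_group], r[!in_group])
  w <- sum(r[in_group])
  use_exact <- switch(exact,
                      always = TRUE,
                      never = FALSE,
                      auto = (n1 + n2) <= exact_max_n)
  p <- if (use_exact) rank_sum_exact_p(r_ord, n1) else rank_sum_normal_p(r_ord, n1)
  list(statistic = w, p_value = p,
       method = if (use_exact) "exact" else "normal")
}

#' One-vs-rest Wilcoxon differential expression
#'
#' For every cluster, tests each gene's expression in the cluster's
#' cells against all remaining cells with the two-sided Wilcoxon
#' rank-sum test (tie-corrected normal approximation; because the
#' one-vs-rest design pools all cells, per-gene ranks are computed once
#' and reused across clusters). Reports, per (gene, cluster):
#' \describe{
#'   \item{p_value, adj_p}{rank-sum p and its Benjamini-Hochberg
#'     adjustment across genes within the cluster}
#'   \item{avg_lfc}{natural-log fold change of mean de-logged normalized
#'     expression, `log((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`}
#'   \item{pct_in, pct_out}{fraction of cells with nonzero expression
#'     inside/outside the cluster}
#'   \item{retained}{whether the gene passes `pct_in >= pct_cutoff`,
#'     `avg_lfc >= lfc_cutoff` and `adj_p < padj_cutoff`}
#' }
#' Retention filters on `pct_in` only; `pct_out` is reported for
#' diagnostics.
#'
#' @param normalized Genes x cells normalized matrix (log1p scale).
#' @param labels Named vector mapping every cell to a cluster; at least
#'   two clusters with at least two cells each.
#' @param pct_cutoff Minimum `pct_in` for retention (default 0.5).
#' @param lfc_cutoff Minimum `avg_lfc` for retention (default 0.5,
#'   natural log).
#' @param padj_cutoff Maximum BH-adjusted p for retention (default 0.05;
#'   set to 1 to disable).
#' @return data.frame of class `marker_table` with one row per
#'   (gene, cluster), plus a `min_pairwise_lfc` column (`NA` until
#'   filled by [rank_markers_min_pairwise_lfc()]).
#' @export
wilcoxon_de <- function(normalized, labels, pct_cutoff = 0.5,
                        lfc_cutoff = 0.5, padj_cutoff = 0.05) {
  cells <- colnames(normalized)
  if (!all(cells %in% names(labels))) {
    stop("every cell must be labelled", call. = FALSE)
  }
  labels <- as.character(labels[cells])
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) {
    stop("at least two clusters are required for one-vs-rest DE",
         call. = FALSE)
  }
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    stop("every cluster needs at least two cells", call. = FALSE)
  }

  X <- as_dense(normalized)
  n <- ncol(X)
  n_genes <- nrow(X)

  # Per-gene ranks over all cells, shared by every one-vs-rest contrast.
  R <- t(apply(X, 1L, rank))
  tie_term <- apply(R, 1L, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  }) / (n * (n - 1))

  ind <- group_indicator(labels)[, clusters, drop = FALSE]
  n_in <- Matrix::colSums(ind)

  W <- R %*% as.matrix(ind)                       # genes x clusters rank sums
  E <- expm1(X)
  sum_in <- E %*% as.matrix(ind)
  pct_in_m <- (X > 0) %*% as.matrix(ind)
  tot_expr <- rowSums(E)
  tot_pos <- rowSums(X > 0)

  rows <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    n1 <- n_in[ci]
    n2 <- n - n1
    mu <- n1 * (n + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (abs(W[, ci] - mu) - 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
    p <- pmin(1, 2 * stats::pnorm(-pmax(z, 0)))
    p[sigma2 <= 0] <- 1
    adj_p <- stats::p.adjust(p, method = "BH")

    mean_in <- sum_in[, ci] / n1
    mean_out <- (tot_expr - sum_in[, ci]) / n2
    avg_lfc <- log((mean_in + 1) / (mean_out + 1))
    pct_in <- pct_in_m[, ci] / n1
    pct_out <- (tot_pos - pct_in_m[, ci]) / n2

    rows[[ci]] <- data.frame(
      gene = rownames(X) %||% as.character(seq_len(n_genes)),
      cluster = clusters[ci],
      p_value = p,
      adj_p = adj_p,
      avg_lfc = avg_lfc,
      pct_in = pct_in,
      pct_out = pct_out,
      min_pairwise_lfc = NA_real_,
      retained = pct_in >= pct_cutoff & avg_lfc >= lfc_cutoff &
        adj_p < padj_cutoff,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  attr(out, "cutoffs") <- list(pct = pct_cutoff, lfc = lfc_cutoff,
                               padj = padj_cutoff)
  out
}
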