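#' Call cell-type matches at a relative-abundance cutoff
#'
#' A mixture matches a reference cell type when its estimated relative
#' fraction is at least `cutoff` (inclusive; default 0.2, the
#' relative-abundance cutoff used for match calling). Mixtures matching
#' no type are flagged unmatched.
#'
#' @param fractions Cell-types x mixtures fraction matrix, or a
#'   `deconv_fit`.
#' @param cutoff Relative-abundance cutoff in (0, 1).
#' @return An object of class `match_table`: list with `matches` (named
#'   list of matched type labels per mixture), `unmatched` (character
#'   vector of mixtures with no match), `fractions` and `cutoff`.
#' @export
threshold_matches <- function(fractions, cutoff = 0.2) {
  if (inherits(fractions, "deconv_fit")) fractions <- coef(fractions)
  fractions <- as_dense(fractions)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff >= 1) {
    stop("'cutoff' must be in (0, 1)", call. = FALSE)
  }
  mix_names <- colnames(fractions) %||% sprintf("mix%02d", seq_len(ncol(fractions)))
  matches <- lapply(seq_len(ncol(fractions)), function(j) {
    rownames(fractions)[fractions[, j] >= cutoff]
  })
  names(matches) <- mix_names
  unmatched <- mix_names[vapply(matches, length, 1L) == 0L]
  structure(list(matches = matches, unmatched = unmatched,
                 fractions = fractions, cutoff = cutoff),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat("Match calls at cutoff ", x$cutoff, ":\n", sep = "")
  for (m in names(x$matches)) {
    types <- x$matches[[m]]
    cat("  ", m, ": ",
        if (length(types) == 0L) "(unmatched)" else paste(types, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Summarize overlap between match sets
#'
#' Counts, for every observed combination of matched cell types, how
#' many mixtures matched exactly that combination (e.g. "3 mixtures
#' matched both embRGP and gliogenic"). Unmatched mixtures are not
#' counted; the counts therefore partition the matched mixtures.
#'
#' @param matches A `match_table`.
#' @return data.frame (`combination`, `n_types`, `count`), sorted by
#'   descending count.
#' @export
overlap_summary <- function(matches) {
  if (!inherits(matches, "match_table")) {
    stop("'matches' must come from threshold_matches()", call. = FALSE)
  }
  sets <- Filter(function(s) length(s) > 0, matches$matches)
  if (length(sets) == 0L) {
    return(data.frame(combination = character(0), n_types = integer(0),
                      count = integer(0)))
  }
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "+"), "")
  tab <- table(keys)
  out <- data.frame(combination = names(tab),
                    n_types = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hierarchically cluster mixtures by their fraction vectors
#'
#' Agglomerative clustering of the mixture columns of a fraction table,
#' as used to order tumour clusters in fraction heatmaps. Euclidean or
#' correlation (1 - Pearson) distances; average, complete or Ward
#' linkage.
#'
#' @param fractions Cell-types x mixtures matrix or `deconv_fit`.
#' @param metric `"euclidean"` or `"correlation"`.
#' @param linkage `"average"`, `"complete"` or `"ward"`.
#' @return List with `order` (mixture labels in leaf order), `hclust`
#'   (the [stats::hclust()] tree) and `newick` (the tree serialized as
#'   a Newick string).
#' @export
hierarchical_cluster_fractions <- function(fractions,
                                           metric = c("euclidean", "correlation"),
                                           linkage = c("average", "complete", "ward")) {
  if (inherits(fractions, "deconv_fit")) fractions <- coef(fractions)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  fractions <- as_dense(fractions)
  if (ncol(fractions) < 2L) {
    stop("need at least two mixtures to cluster", call. = FALSE)
  }
  pts <- t(fractions)
  d <- if (metric == "euclidean") {
    stats::dist(pts)
  } else {
    stats::as.dist(1 - stats::cor(fractions))
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(d, method = method)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(order = hc$labels[hc$order], hclust = hc, newick = newick)
}

#' Ground-truth recovery metrics for a synthetic deconvolution
#'
#' Compares estimated fractions with the known ground truth of a
#' synthetic mixture set: per-type mean absolute error, overall Pearson
#' correlation across all (type, mixture) pairs, and the sensitivity
#' and specificity of match calling at `cutoff` (a pair is a positive
#' when its true fraction is at least the cutoff).
#'
#' @param estimated Cell-types x mixtures fraction matrix or
#'   `deconv_fit` (whose attached truth is used when `truth` is
#'   missing).
#' @param truth Cell-types x mixtures ground-truth matrix with
#'   identical labels and column order.
#' @param cutoff Match cutoff (default 0.2).
#' @return An object of class `recovery_report`: list with
#'   `per_type_mae` (named vector), `mae` (overall mean absolute
#'   error), `pearson_r`, `sensitivity`, `specificity`, `cutoff`.
#' @export
recovery_metrics <- function(estimated, truth = NULL, cutoff = 0.2) {
  if (inherits(estimated, "deconv_fit")) {
    truth <- truth %||% estimated$truth
    estimated <- coef(estimated)
  }
  if (is.null(truth)) {
    stop("ground truth is required for recovery metrics", call. = FALSE)
  }
  estimated <- as_dense(estimated)
  truth <- as_dense(truth)
  row_diff <- c(setdiff(rownames(estimated), rownames(truth)),
                setdiff(rownames(truth), rownames(estimated)))
  col_diff <- c(setdiff(colnames(estimated), colnames(truth)),
                setdiff(colnames(truth), colnames(estimated)))
  if (length(row_diff) > 0 || length(col_diff) > 0) {
    stop("label mismatch between estimate and truth: ",
         paste(unique(c(row_diff, col_diff)), collapse = ", "),
         call. = FALSE)
  }
  truth <- truth[rownames(estimated), colnames(estimated), drop = FALSE]

  err <- abs(estimated - truth)
  pred_pos <- estimated >= cutoff
  true_pos <- truth >= cutoff
  tp <- sum(pred_pos & true_pos)
  fn <- sum(!pred_pos & true_pos)
  tn <- sum(!pred_pos & !true_pos)
  fp <- sum(pred_pos & !true_pos)
  structure(list(
    per_type_mae = rowMeans(err),
    mae = mean(err),
    pearson_r = if (stats::sd(estimated) == 0 || stats::sd(truth) == 0) {
      NA_real_
    } else {
      stats::cor(as.numeric(estimated), as.numeric(truth))
    },
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    cutoff = cutoff
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Ground-truth recovery (cutoff ", x$cutoff, "):\n", sep = "")
  cat("  overall MAE: ", format(x$mae, digits = 4),
      "   Pearson r: ", format(x$pearson_r, digits = 4), "\n", sep = "")
  cat("  match sensitivity: ", format(x$sensitivity, digits = 4),
      "   specificity: ", format(x$specificity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Export a deconvolution run as plain-text report files
#'
#' Writes, into `out_dir`: `fractions.tsv` (types x mixtures, mixture
#' columns in hierarchically clustered order when there are at least
#' two), `matches.tsv`, `overlap.tsv`, `dendrogram.nwk` and
#' `run_info.txt` (engine and configuration). Outputs are deterministic
#' functions of the inputs, so repeated runs are byte-identical.
#'
#' @param fit A `deconv_fit`.
#' @param matches Optional `match_table` (computed at cutoff 0.2 when
#'   missing).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
export_report <- function(fit, matches = NULL, out_dir) {
  if (!inherits(fit, "deconv_fit")) {
    stop("'fit' must be a deconv_fit", call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  matches <- matches %||% threshold_matches(fit)
  fr <- coef(fit)
  newick <- ""
  if (ncol(fr) >= 2L) {
    clust <- hierarchical_cluster_fractions(fr)
    fr <- fr[, clust$order, drop = FALSE]
    newick <- clust$newick
  }

  paths <- file.path(out_dir, c("fractions.tsv", "matches.tsv", "overlap.tsv",
                                "dendrogram.nwk", "run_info.txt"))
  write_matrix_tsv(fr, paths[1], id_column = "cell_type")

  match_df <- data.frame(
    mixture = names(matches$matches),
    matched_types = vapply(matches$matches, paste, "", collapse = ","),
    unmatched = names(matches$matches) %in% matches$unmatched,
    stringsAsFactors = FALSE
  )
  write_tsv_file(match_df, paths[2])
  write_tsv_file(overlap_summary(matches), paths[3])
  writeLines(newick, paths[4])
  cfg <- fit$config
  writeLines(c(
    paste0("engine: ", fit$engine),
    paste0("cutoff: ", matches$cutoff),
    paste0("nu_grid: ", paste(cfg$nu_grid, collapse = ",")),
    paste0("standardize: ", cfg$standardize),
    paste0("dwls_damping: ", cfg$dwls_damping),
    paste0("max_iter: ", cfg$max_iter),
    paste0("tol: ", cfg$tol),
    paste0("n_genes: ", nrow(fit$signature)),
    paste0("n_types: ", nrow(fr)),
    paste0("n_mixtures: ", ncol(fr))
  ), paths[5])
  invisible(paths)
}
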