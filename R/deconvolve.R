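#' Deconvolve pseudobulk mixtures into reference cell-type fractions
#'
#' The package's central fitting function. Each mixture column is
#' regressed on the signature matrix with the chosen engine
#' (nu-support-vector regression by default, or non-negative least
#' squares, or damped weighted least squares), the raw coefficients are
#' projected onto the simplex ([postprocess_fractions()]), and the fit
#' of the reconstruction `S %*% w` to the observed mixture is scored by
#' RMSE and Pearson correlation ([evaluate_fit()]). The estimated
#' columns are the "relative fractions" of the reference cell types in
#' each mixture.
#'
#' @param signature Genes x cell-types matrix (a `signature_matrix` or
#'   any labelled matrix of reference profiles).
#' @param mixtures Genes x mixtures matrix of pseudobulk profiles, or a
#'   `mixture_set` from [simulate_mixtures()] (its ground truth is then
#'   kept on the fit for [recovery_metrics()]).
#' @param engine `"nusvr"`, `"nnls"` or `"dwls"`.
#' @param nu_grid Candidate nu values for the nu-SVR engine.
#' @param standardize Z-score signature and mixture before nu-SVR.
#' @param dwls_damping,max_iter,tol DWLS engine controls; see
#'   [deconvolve_dwls()].
#' @param min_shared Minimum shared-gene count, see [align_features()].
#' @return An object of class `deconv_fit`: a list with
#'   \describe{
#'     \item{fractions}{cell-types x mixtures simplex matrix}
#'     \item{stats}{per-mixture data.frame: `mixture`, `engine`,
#'       `nu`/`iterations`, `rmse`, `pearson_r`, `degenerate`}
#'     \item{signature, mixtures}{the aligned inputs}
#'     \item{truth}{ground-truth fractions when supplied, else `NULL`}
#'   }
#' @examples
#' atlas <- simulate_atlas(atlas_spec(n_cell_types = 3, cells_per_type = 40,
#'                                    n_genes = 300, markers_per_type = 20))
#' norm <- normalize_log1p(atlas$counts)
#' labels <- with(atlas$annotation, setNames(cluster, cell_id))
#' sig <- pseudobulk_cluster_means(norm, labels)
#' truth <- simulate_fraction_truth(colnames(sig), n_mixtures = 5, seed = 2)
#' mix <- simulate_mixtures(sig, truth, noise_sd = 0, seed = 3)
#' fit <- deconvolve(sig, mix, engine = "nnls", min_shared = 10)
#' round(coef(fit), 3)
#' @seealso [threshold_matches()], [recovery_metrics()]
#' @export
deconvolve <- function(signature, mixtures,
                       engine = c("nusvr", "nnls", "dwls"),
                       nu_grid = c(0.25, 0.5, 0.75),
                       standardize = TRUE,
                       dwls_damping = 1e-4,
                       max_iter = 100L,
                       tol = 1e-8,
                       min_shared = 50L) {
  engine <- match.arg(engine)
  aligned <- align_features(signature, mixtures, min_shared = min_shared)
  S <- aligned$signature
  M <- aligned$mixtures
  n_mix <- ncol(M)
  mix_names <- colnames(M) %||% sprintf("mix%02d", seq_len(n_mix))

  fractions <- matrix(0, nrow = ncol(S), ncol = n_mix,
                      dimnames = list(colnames(S), mix_names))
  stats_rows <- vector("list", n_mix)
  for (j in seq_len(n_mix)) {
    m <- M[, j]
    res <- switch(engine,
      nnls = deconvolve_nnls(S, m),
      nusvr = deconvolve_nusvr(S, m, nu_grid = nu_grid,
                               standardize = standardize),
      dwls = deconvolve_dwls(S, m, damping = dwls_damping,
                             max_iter = max_iter, tol = tol))
    frac <- postprocess_fractions(res$w)
    degenerate <- attr(frac, "degenerate") ||
      isTRUE(res$meta$degenerate %||% FALSE)
    fractions[, j] <- frac
    fit <- evaluate_fit(S, as.numeric(frac), m)
    stats_rows[[j]] <- data.frame(
      mixture = mix_names[j],
      engine = engine,
      nu = res$meta$nu %||% NA_real_,
      iterations = res$meta$iterations %||% NA_integer_,
      rmse = fit$rmse,
      pearson_r = fit$pearson_r,
      degenerate = degenerate,
      stringsAsFactors = FALSE
    )
  }
  stats_df <- do.call(rbind, stats_rows)
  rownames(stats_df) <- NULL

  structure(list(fractions = fractions, stats = stats_df,
                 signature = S, mixtures = M, truth = aligned$truth,
                 engine = engine,
                 config = list(nu_grid = nu_grid, standardize = standardize,
                               dwls_damping = dwls_damping,
                               max_iter = max_iter, tol = tol,
                               min_shared = min_shared)),
            class = "deconv_fit")
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat("Cell-type deconvolution fit (engine: ", x$engine, ")\n", sep = "")
  cat("  ", ncol(x$fractions), " mixture(s) x ", nrow(x$fractions),
      " cell type(s) on ", nrow(x$signature), " shared genes\n", sep = "")
  cat("  median reconstruction r: ",
      format(stats::median(x$stats$pearson_r, na.rm = TRUE), digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.deconv_fit <- function(object, ...) {
  top_idx <- apply(object$fractions, 2L, which.max)
  s <- object$stats
  s$top_type <- rownames(object$fractions)[top_idx]
  s$top_fraction <- object$fractions[cbind(top_idx, seq_len(ncol(object$fractions)))]
  structure(list(engine = object$engine, table = s),
            class = "summary.deconv_fit")
}

#' @export
print.summary.deconv_fit <- function(x, ...) {
  cat("Deconvolution summary (engine: ", x$engine, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Extract estimated cell-type fractions
#'
#' @param object A `deconv_fit`.
#' @param ... Ignored.
#' @return Cell-types x mixtures matrix of relative fractions.
#' @export
coef.deconv_fit <- function(object, ...) {
  object$fractions
}

#' Reconstructed mixtures implied by the estimated fractions
#'
#' @param object A `deconv_fit`.
#' @param ... Ignored.
#' @return Genes x mixtures matrix `S %*% W`.
#' @export
fitted.deconv_fit <- function(object, ...) {
  object$signature %*% object$fractions
}

#' @export
residuals.deconv_fit <- function(object, ...) {
  object$mixtures - fitted(object)
}

#' Estimate fractions for new mixtures with a fitted configuration
#'
#' @param object A `deconv_fit`.
#' @param newdata Genes x mixtures matrix (or `mixture_set`); defaults
#'   to the fitted mixtures.
#' @param ... Ignored.
#' @return Cell-types x mixtures fraction matrix.
#' @export
predict.deconv_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fractions)
  cfg <- object$config
  refit <- deconvolve(object$signature, newdata, engine = object$engine,
                      nu_grid = cfg$nu_grid, standardize = cfg$standardize,
                      dwls_damping = cfg$dwls_damping,
                      max_iter = cfg$max_iter, tol = cfg$tol,
                      min_shared = cfg$min_shared)
  refit$fractions
}

#' Heatmap of estimated fractions
#'
#' Draws the cell-types x mixtures fraction matrix as a heatmap with
#' mixtures ordered by hierarchical clustering of their fraction
#' vectors (uses \pkg{pheatmap} when installed, otherwise
#' [stats::heatmap()]).
#'
#' @param x A `deconv_fit`.
#' @param cluster_metric,cluster_linkage Passed to
#'   [hierarchical_cluster_fractions()].
#' @param ... Passed to the underlying heatmap function.
#' @export
plot.deconv_fit <- function(x, cluster_metric = "euclidean",
                            cluster_linkage = "average", ...) {
  fr <- x$fractions
  if (ncol(fr) >= 2L) {
    ord <- hierarchical_cluster_fractions(fr, metric = cluster_metric,
                                          linkage = cluster_linkage)$order
    fr <- fr[, ord, drop = FALSE]
  }
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(fr, cluster_cols = FALSE, cluster_rows = FALSE, ...)
  } else {
    stats::heatmap(fr, Rowv = NA, Colv = NA, scale = "none", ...)
  }
  invisible(x)
}
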