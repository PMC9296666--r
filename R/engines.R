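# Fraction-estimation engines. All engines take an aligned signature
# (genes x types) and one mixture column, and return raw non-negative
# coefficient estimates; postprocess_fractions() maps those onto the
# simplex ("relative fractions").

#' Restrict a signature and mixture set to their shared genes
#'
#' Intersects the gene identifiers of the signature matrix and the
#' mixtures and reorders both to the same row order. Deconvolution is
#' only meaningful on this shared feature space; an intersection below
#' `min_shared` genes aborts with the observed counts.
#'
#' @param signature Genes x cell-types matrix.
#' @param mixtures Genes x mixtures matrix, or a `mixture_set`.
#' @param min_shared Minimum acceptable intersection size (default 50).
#' @return List with `signature` and `mixtures` (both plain matrices,
#'   identical rownames) and `truth` (carried over when `mixtures` was a
#'   `mixture_set`, else `NULL`).
#' @export
align_features <- function(signature, mixtures, min_shared = 50L) {
  truth <- NULL
  if (inherits(mixtures, "mixture_set")) {
    truth <- mixtures$truth
    mixtures <- mixtures$expr
  }
  signature <- as_dense(signature)
  mixtures <- as_dense(mixtures)
  shared <- intersect(rownames(signature), rownames(mixtures))
  if (length(shared) < min_shared) {
    stop(sprintf(paste0("only %d shared gene(s) between signature (%d) and ",
                        "mixtures (%d); need at least %d"),
                 length(shared), nrow(signature), nrow(mixtures), min_shared),
         call. = FALSE)
  }
  list(signature = signature[shared, , drop = FALSE],
       mixtures = mixtures[shared, , drop = FALSE],
       truth = truth)
}

#' Non-negative least squares deconvolution of one mixture
#'
#' Solves `min || S w - m ||^2` subject to `w >= 0` (Lawson-Hanson
#' active set). Serves both as a fast baseline engine and as the oracle
#' the other engines are compared against on noise-free mixtures.
#'
#' @param signature Aligned genes x types matrix.
#' @param mixture_column Numeric vector (one mixture, aligned genes).
#' @return List with `w` (raw non-negative coefficients, named by type)
#'   and `meta` (empty list).
#' @export
deconvolve_nnls <- function(signature, mixture_column) {
  S <- as_dense(signature)
  if (length(mixture_column) != nrow(S)) {
    stop("mixture length does not match signature genes", call. = FALSE)
  }
  cond <- kappa(S, exact = FALSE)
  if (!is.finite(cond) || cond > 1e10) {
    warning("signature matrix is (near) rank-deficient; condition number ",
            format(cond, digits = 3), call. = FALSE)
  }
  w <- if (all(mixture_column == 0)) {
    rep(0, ncol(S))
  } else {
    pracma::lsqnonneg(S, as.numeric(mixture_column))$x
  }
  list(w = stats::setNames(pmax(w, 0), colnames(S)), meta = list())
}

#' nu-support-vector-regression deconvolution of one mixture
#'
#' The regression core of the CIBERSORT-style engine family: fits a
#' linear nu-SVR of the mixture on the signature columns for each nu in
#' `nu_grid`, extracts the primal coefficients, clips negatives to
#' zero, and keeps the nu whose sum-to-one-normalized coefficients best
#' reconstruct the (standardized) mixture by RMSE. Ties break toward
#' the smaller nu. When `standardize` is `TRUE` the signature is
#' z-scored as a whole matrix and the mixture as a vector — a shared
#' affine transform that leaves the relative coefficient scale intact.
#'
#' @param signature Aligned genes x types matrix.
#' @param mixture_column Numeric vector (one mixture).
#' @param nu_grid Candidate nu values in (0, 1).
#' @param standardize Z-score signature and mixture before fitting.
#' @return List with `w` (raw clipped coefficients) and `meta`
#'   (`nu`, `rmse`, `r` of the chosen fit).
#' @export
deconvolve_nusvr <- function(signature, mixture_column,
                             nu_grid = c(0.25, 0.5, 0.75),
                             standardize = TRUE) {
  S <- as_dense(signature)
  m <- as.numeric(mixture_column)
  if (length(nu_grid) == 0L || any(nu_grid <= 0 | nu_grid >= 1)) {
    stop("'nu_grid' must be a non-empty set of values in (0, 1)",
         call. = FALSE)
  }
  if (stats::sd(m) == 0) {
    return(list(w = stats::setNames(rep(0, ncol(S)), colnames(S)),
                meta = list(nu = NA_real_, rmse = NA_real_, r = NA_real_,
                            degenerate = TRUE)))
  }
  if (standardize) {
    S_fit <- (S - mean(S)) / stats::sd(as.vector(S))
    m_fit <- (m - mean(m)) / stats::sd(m)
  } else {
    S_fit <- S
    m_fit <- m
  }
  best <- NULL
  for (nu in sort(nu_grid)) {
    fit <- tryCatch(
      e1071::svm(S_fit, m_fit, type = "nu-regression", kernel = "linear",
                 nu = nu, scale = FALSE),
      error = function(e) {
        warning(sprintf("nu-SVR failed at nu = %g: %s", nu,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    w <- pmax(w, 0)
    if (sum(w) > 0) {
      recon <- S_fit %*% (w / sum(w))
      rmse <- sqrt(mean((recon - m_fit)^2))
      r <- suppressWarnings(stats::cor(as.numeric(recon), m_fit))
    } else {
      rmse <- sqrt(mean(m_fit^2))
      r <- NA_real_
    }
    # strict < keeps the smallest nu on ties (grid is sorted ascending)
    if (is.null(best) || rmse < best$meta$rmse) {
      best <- list(w = stats::setNames(w, colnames(S)),
                   meta = list(nu = nu, rmse = rmse, r = r))
    }
  }
  if (is.null(best)) {
    stop("nu-SVR failed for every nu in the grid", call. = FALSE)
  }
  best
}

#' Damped weighted least squares deconvolution of one mixture
#'
#' Iteratively reweighted non-negative least squares: starting from the
#' plain NNLS solution, genes are reweighted by
#' `1 / max((S w)^2, damping)` — emphasising genes the current fit
#' predicts to be lowly expressed — and the weighted NNLS problem is
#' re-solved until the coefficients change by less than `tol`
#' (relative, sup-norm) or `max_iter` is reached.
#'
#' @param signature Aligned genes x types matrix.
#' @param mixture_column Numeric vector (one mixture).
#' @param damping Lower bound on the squared fitted value in the weight
#'   denominator; keeps weights finite (default 1e-4).
#' @param max_iter Maximum reweighting iterations (default 100).
#' @param tol Relative convergence tolerance (default 1e-8).
#' @return List with `w` and `meta` (`iterations`, `converged`).
#' @export
deconvolve_dwls <- function(signature, mixture_column, damping = 1e-4,
                            max_iter = 100L, tol = 1e-8) {
  S <- as_dense(signature)
  m <- as.numeric(mixture_column)
  check_positive_scalar(damping, "damping")
  check_positive_scalar(max_iter, "max_iter", integer = TRUE)
  check_positive_scalar(tol, "tol")
  if (all(m == 0)) {
    return(list(w = stats::setNames(rep(0, ncol(S)), colnames(S)),
                meta = list(iterations = 0L, converged = TRUE)))
  }
  w <- pracma::lsqnonneg(S, m)$x
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    fitted_vals <- as.numeric(S %*% w)
    wt <- 1 / pmax(fitted_vals^2, damping)
    sw <- sqrt(wt)
    w_new <- pracma::lsqnonneg(S * sw, m * sw)$x
    delta <- max(abs(w_new - w)) / max(max(abs(w)), .Machine$double.eps)
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("DWLS did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  list(w = stats::setNames(pmax(w, 0), colnames(S)),
       meta = list(iterations = it, converged = converged))
}

#' Project raw coefficients onto the simplex of relative fractions
#'
#' Clips negative coefficients to zero and divides by the sum, giving
#' non-negative fractions that sum to one. An all-zero (or all-negative)
#' input cannot be normalized and is returned as all zeros with a
#' `degenerate` attribute.
#'
#' @param raw Numeric coefficient vector.
#' @return Simplex vector of the same length/names, with attribute
#'   `degenerate` (logical).
#' @export
postprocess_fractions <- function(raw) {
  w <- pmax(as.numeric(raw), 0)
  names(w) <- names(raw)
  s <- sum(w)
  if (s > 0) {
    out <- w / s
    attr(out, "degenerate") <- FALSE
  } else {
    out <- w
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Goodness of fit of estimated fractions for one mixture
#'
#' Reconstructs the mixture as `S %*% fractions` and reports the root
#' mean squared error and Pearson correlation against the observed
#' mixture over genes. A constant reconstruction has no defined
#' correlation and yields `pearson_r = NA`.
#'
#' @param signature Aligned genes x types matrix.
#' @param fractions Coefficient vector (types).
#' @param mixture_column Observed mixture vector (genes).
#' @return List with `rmse` and `pearson_r`.
#' @export
evaluate_fit <- function(signature, fractions, mixture_column) {
  S <- as_dense(signature)
  recon <- as.numeric(S %*% as.numeric(fractions))
  m <- as.numeric(mixture_column)
  rmse <- sqrt(mean((recon - m)^2))
  r <- if (stats::sd(recon) == 0 || stats::sd(m) == 0) {
    NA_real_
  } else {
    stats::cor(recon, m)
  }
  list(rmse = rmse, pearson_r = r)
}
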