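#' Cell-level quality-control thresholds
#'
#' Bundles the QC rules applied to raw count matrices: a minimum number
#' of detected genes per cell (cells below it are treated as empty
#' droplets/nuclei), a per-sample maximum mitochondrial content, and a
#' high-count doublet rule flagging cells whose detected-gene count
#' exceeds the per-sample median by more than `doublet_k` standard
#' deviations.
#'
#' @param min_genes Minimum detected genes; cells with fewer are removed
#'   (strict `<`). Default 1000.
#' @param mito_max Maximum mitochondrial count fraction, either a single
#'   value or a named vector with one value per sample (the threshold is
#'   set per sample). Cells strictly above it are removed. Default 0.10.
#' @param doublet_k SD multiplier for the high-count rule; 4 by default,
#'   values of 4-5 are typical.
#' @param mito_gene_prefix Case-insensitive gene-identifier prefix that
#'   marks mitochondrial genes (default `"mt-"`).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 1000L, mito_max = 0.10,
                          doublet_k = 4, mito_gene_prefix = "mt-") {
  check_positive_scalar(min_genes, "min_genes", integer = TRUE)
  check_positive_scalar(doublet_k, "doublet_k")
  if (!is.numeric(mito_max) || any(mito_max <= 0) || any(mito_max > 1)) {
    stop("'mito_max' values must be in (0, 1]", call. = FALSE)
  }
  structure(list(min_genes = as.integer(min_genes), mito_max = mito_max,
                 doublet_k = doublet_k, mito_gene_prefix = mito_gene_prefix),
            class = "qc_thresholds")
}

#' Filter low-quality cells from a count matrix
#'
#' Applies, in order: (1) removal of cells with fewer than `min_genes`
#' detected genes; (2) removal of cells whose mitochondrial count
#' fraction exceeds the sample's `mito_max`; (3) removal of putative
#' doublets — cells whose detected-gene count exceeds
#' `median + doublet_k * SD`, with median and SD computed per sample on
#' the cells surviving the first two rules. The doublet rule is applied
#' exactly once (no iteration), so the filter is deterministic.
#'
#' Mitochondrial content is computed on raw counts (mitochondrial counts
#' over total counts).
#'
#' @param counts Genes x cells count matrix (sparse or dense) with gene
#'   and cell identifiers as dimnames.
#' @param thresholds A [qc_thresholds()] object.
#' @param sample_of_cell Named character vector (or factor) giving the
#'   sample of every cell; must cover all cells.
#' @return A list with `counts` (the filtered matrix) and `report`, a
#'   data.frame with columns `sample`, `rule`, `cells_removed`.
#' @export
qc_filter_cells <- function(counts, thresholds = qc_thresholds(),
                            sample_of_cell) {
  if (!inherits(thresholds, "qc_thresholds")) {
    stop("'thresholds' must be a qc_thresholds() object", call. = FALSE)
  }
  cells <- colnames(counts)
  if (is.null(cells) || is.null(rownames(counts))) {
    stop("'counts' must carry gene and cell identifiers", call. = FALSE)
  }
  sample_of_cell <- stats::setNames(as.character(sample_of_cell),
                                    names(sample_of_cell))
  missing_cells <- setdiff(cells, names(sample_of_cell))
  if (length(missing_cells) > 0) {
    stop("cell(s) without sample assignment: ",
         paste(utils::head(missing_cells, 5), collapse = ", "), call. = FALSE)
  }
  sample_of_cell <- sample_of_cell[cells]
  samples <- sort(unique(sample_of_cell))

  mito_max <- thresholds$mito_max
  if (length(mito_max) > 1L || !is.null(names(mito_max))) {
    miss <- setdiff(samples, names(mito_max))
    if (length(miss) > 0) {
      stop("no 'mito_max' threshold for sample(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    mito_of_sample <- mito_max[samples]
  } else {
    mito_of_sample <- stats::setNames(rep(mito_max, length(samples)), samples)
  }

  detected <- Matrix::colSums(counts > 0)
  totals <- Matrix::colSums(counts)
  is_mito <- startsWith(tolower(rownames(counts)),
                        tolower(thresholds$mito_gene_prefix))
  mito_frac <- if (any(is_mito)) {
    Matrix::colSums(counts[is_mito, , drop = FALSE]) / pmax(totals, 1)
  } else {
    rep(0, length(cells))
  }

  rm_min <- detected < thresholds$min_genes
  rm_mito <- !rm_min & mito_frac > mito_of_sample[sample_of_cell]

  keep_after2 <- !(rm_min | rm_mito)
  rm_doublet <- rep(FALSE, length(cells))
  for (s in samples) {
    in_s <- keep_after2 & sample_of_cell == s
    if (!any(in_s)) next
    med <- stats::median(detected[in_s])
    sdev <- stats::sd(detected[in_s])
    if (is.na(sdev)) sdev <- 0
    rm_doublet[in_s] <- detected[in_s] > med + thresholds$doublet_k * sdev
  }

  report <- do.call(rbind, lapply(samples, function(s) {
    in_s <- sample_of_cell == s
    data.frame(sample = s,
               rule = c("min_genes", "mito_fraction", "high_count_doublet"),
               cells_removed = c(sum(rm_min & in_s), sum(rm_mito & in_s),
                                 sum(rm_doublet & in_s)),
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL

  keep <- !(rm_min | rm_mito | rm_doublet)
  out <- counts[, keep, drop = FALSE]
  if (ncol(out) == 0L) {
    warning("all cells removed by QC filtering", call. = FALSE)
  }
  list(counts = out, report = report)
}

# The six sex-linked genes excluded to remove sex-specific effects.
SEX_GENES <- c("Xist", "Tsix", "Eif2s3y", "Ddx3y", "Uty", "Kdm5d")

#' Remove sex-linked genes
#'
#' Drops the rows for the six sex-specific genes (Xist, Tsix, Eif2s3y,
#' Ddx3y, Uty, Kdm5d), matched case-insensitively. Genes not present are
#' silently ignored.
#'
#' @param x Genes x cells (or genes x clusters) matrix with gene ids as
#'   rownames.
#' @return The matrix without the sex-gene rows.
#' @export
remove_sex_genes <- function(x) {
  if (is.null(rownames(x))) stop("'x' must have gene rownames", call. = FALSE)
  keep <- !(tolower(rownames(x)) %in% tolower(SEX_GENES))
  x[keep, , drop = FALSE]
}

#' Global-scaling log normalization
#'
#' Library-size normalizes each cell to a fixed scale and applies
#' `log1p`: entry (g, c) becomes
#' `log(1 + count(g, c) / total(c) * scale_factor)`. This is the global
#' scaling normalization conventionally used for single-cell counts; the
#' default scale factor is 10,000.
#'
#' @param counts Genes x cells count matrix (sparse or dense).
#' @param scale_factor Positive scale applied after library-size
#'   division.
#' @return Normalized matrix of the same shape (sparse in, sparse out),
#'   with attributes `scale_factor` and `transform = "log1p"`.
#' @export
normalize_log1p <- function(counts, scale_factor = 1e4) {
  check_positive_scalar(scale_factor, "scale_factor")
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0]
    stop("cell(s) with zero total count: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (inherits(counts, "CsparseMatrix")) {
    out <- counts
    out@x <- log1p(out@x / rep.int(totals, diff(out@p)) * scale_factor)
  } else {
    dense <- as_dense(counts)
    out <- log1p(sweep(dense, 2, totals, "/") * scale_factor)
  }
  attr(out, "scale_factor") <- scale_factor
  attr(out, "transform") <- "log1p"
  out
}

#' Refine G1 cell-cycle calls into G0 versus G1
#'
#' Upstream classifiers assign G1/S/G2M phases but do not distinguish
#' quiescent (G0) from cycling G1 cells. Cells called G1 upstream are
#' relabelled G1 only if any gate gene (by default the proliferation
#' markers Top2a and Mki67, matched case-insensitively) has normalized
#' expression strictly above `threshold`; otherwise they become G0.
#' S and G2M calls pass through unchanged.
#'
#' @param normalized Genes x cells normalized matrix (log1p scale).
#' @param phase_calls Named character vector of upstream calls (values
#'   `G1`, `S`, `G2M`) covering all cells.
#' @param gate_genes Proliferation gate genes.
#' @param threshold Expression gate (log1p scale), strict `>`.
#' @return Named character vector of `G0`/`G1`/`S`/`G2M` calls.
#' @export
gate_g0_g1 <- function(normalized, phase_calls,
                       gate_genes = c("Top2a", "Mki67"), threshold = 1) {
  cells <- colnames(normalized)
  if (!all(cells %in% names(phase_calls))) {
    stop("'phase_calls' must cover every cell", call. = FALSE)
  }
  phase_calls <- as.character(phase_calls[cells])
  hit <- match(tolower(gate_genes), tolower(rownames(normalized)))
  if (anyNA(hit)) {
    warning("gate gene(s) not found (treated as unexpressed): ",
            paste(gate_genes[is.na(hit)], collapse = ", "), call. = FALSE)
    hit <- hit[!is.na(hit)]
  }
  gate_high <- if (length(hit) > 0) {
    gm <- as_dense(normalized[hit, , drop = FALSE])
    apply(gm > threshold, 2, any)
  } else {
    rep(FALSE, length(cells))
  }
  out <- phase_calls
  is_g1 <- phase_calls == "G1"
  out[is_g1 & !gate_high] <- "G0"
  stats::setNames(out, cells)
}

#' Per-cluster pseudobulk average expression
#'
#' Collapses a genes x cells normalized matrix to a genes x clusters
#' matrix of arithmetic means over each cluster's cells — the pseudobulk
#' profile used both for signature columns (reference side) and as the
#' mixture to deconvolve (tumour side).
#'
#' @param normalized Genes x cells matrix.
#' @param labels Named vector mapping every cell to a cluster.
#' @return Genes x clusters dense matrix.
#' @export
pseudobulk_cluster_means <- function(normalized, labels) {
  cells <- colnames(normalized)
  if (!all(cells %in% names(labels))) {
    stop("unlabelled cell(s): ",
         paste(utils::head(setdiff(cells, names(labels)), 5), collapse = ", "),
         call. = FALSE)
  }
  labels <- as.character(labels[cells])
  if (anyNA(labels) || length(labels) == 0L) {
    stop("every cell must carry a non-missing cluster label", call. = FALSE)
  }
  ind <- group_indicator(labels)
  sums <- normalized %*% ind
  means <- sweep(as_dense(sums), 2, Matrix::colSums(ind), "/")
  rownames(means) <- rownames(normalized)
  means
}
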