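#' Specification of a synthetic reference atlas
#'
#' Describes a multi-timepoint single-cell reference atlas in which each
#' cell type carries a disjoint module of planted marker genes. Counts are
#' negative binomial: non-marker genes share a common baseline mean, and a
#' type's markers have their mean multiplied by `marker_fold_change` in
#' cells of that type only. Per-cell library-size variation is log-normal.
#'
#' The default configuration emulates a developmental neural atlas with
#' temporally restricted precursor states: an embryonic radial-glial
#' precursor (`embRGP`) and gliogenic precursor at embryonic/early
#' postnatal timepoints, and quiescent/active adult neural stem cells
#' (`qNSC`, `aNSC`) restricted to the adult timepoint, alongside
#' differentiated types.
#'
#' @param n_cell_types Number of cell types.
#' @param cells_per_type Cells simulated per type (scalar or one per type).
#' @param n_genes Total number of genes.
#' @param markers_per_type Number of marker genes planted per type; marker
#'   sets of distinct types are disjoint, so
#'   `markers_per_type * n_cell_types` must not exceed `n_genes`.
#' @param marker_fold_change Multiplicative shift (> 1) of a type's marker
#'   means in that type's cells.
#' @param type_labels Optional character vector of type names. When
#'   `n_cell_types` is 8 (the default) a developmental-atlas naming is
#'   used; otherwise `type01`, `type02`, ...
#' @param timepoint_of_type Optional named character vector mapping each
#'   type label to a timepoint label.
#' @param baseline_mean Negative-binomial mean of non-marker genes.
#' @param dispersion Negative-binomial size parameter (smaller = noisier).
#' @param library_size_scale Log-normal sdlog of per-cell library-size
#'   factors (the factors have expectation 1).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#'
#' @return An object of class `atlas_spec`.
#' @seealso [simulate_atlas()]
#' @export
atlas_spec <- function(n_cell_types = 8L,
                       cells_per_type = 200L,
                       n_genes = 2000L,
                       markers_per_type = 50L,
                       marker_fold_change = 8,
                       type_labels = NULL,
                       timepoint_of_type = NULL,
                       baseline_mean = 0.5,
                       dispersion = 2,
                       library_size_scale = 0.25,
                       seed = 1L) {
  check_positive_scalar(n_cell_types, "n_cell_types", integer = TRUE)
  check_positive_scalar(n_genes, "n_genes", integer = TRUE)
  check_positive_scalar(markers_per_type, "markers_per_type", integer = TRUE)
  check_positive_scalar(baseline_mean, "baseline_mean")
  check_positive_scalar(dispersion, "dispersion")
  check_positive_scalar(library_size_scale, "library_size_scale",
                        strict = FALSE)
  if (!is.numeric(marker_fold_change) || length(marker_fold_change) != 1L ||
      marker_fold_change <= 1) {
    stop("'marker_fold_change' must be > 1", call. = FALSE)
  }
  if (markers_per_type * n_cell_types > n_genes) {
    stop("invariant violated: markers_per_type * n_cell_types must be <= n_genes",
         call. = FALSE)
  }
  if (any(cells_per_type <= 0) || any(cells_per_type != as.integer(cells_per_type))) {
    stop("'cells_per_type' must be positive integers", call. = FALSE)
  }
  cells_per_type <- rep_len(as.integer(cells_per_type), n_cell_types)

  if (is.null(type_labels)) {
    type_labels <- if (n_cell_types == 8L) {
      c("embRGP", "gliogenic", "OPC", "astrocyte",
        "neuron", "aNSC", "qNSC", "microglia")
    } else {
      sprintf("type%02d", seq_len(n_cell_types))
    }
  }
  type_labels <- as.character(type_labels)
  if (length(type_labels) != n_cell_types || anyDuplicated(type_labels)) {
    stop("'type_labels' must be ", n_cell_types, " unique labels",
         call. = FALSE)
  }

  if (is.null(timepoint_of_type)) {
    # embryonic -> postnatal -> adult axis; adult NSC states live at the
    # last timepoint, embryonic precursors at the first.
    tps <- c("E12", "E16", "P0", "P13", "P111")
    default_tp <- tps[pmin(length(tps), ceiling(seq_len(n_cell_types) /
                                                  n_cell_types * length(tps)))]
    if (n_cell_types == 8L) {
      default_tp <- c("E12", "E16", "P0", "P13", "P13", "P111", "P111", "P111")
    }
    timepoint_of_type <- stats::setNames(default_tp, type_labels)
  }
  if (!all(type_labels %in% names(timepoint_of_type))) {
    stop("'timepoint_of_type' must name every cell type", call. = FALSE)
  }

  structure(list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type = cells_per_type,
    n_genes = as.integer(n_genes),
    markers_per_type = as.integer(markers_per_type),
    marker_fold_change = marker_fold_change,
    type_labels = type_labels,
    timepoint_of_type = timepoint_of_type[type_labels],
    baseline_mean = baseline_mean,
    dispersion = dispersion,
    library_size_scale = library_size_scale,
    seed = as.integer(seed)
  ), class = "atlas_spec")
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat("Synthetic atlas spec:", x$n_cell_types, "cell types,",
      sum(x$cells_per_type), "cells,", x$n_genes, "genes\n")
  cat("  markers/type:", x$markers_per_type,
      " fold change:", x$marker_fold_change,
      " NB(mean=", x$baseline_mean, ", size=", x$dispersion, ")\n", sep = "")
  invisible(x)
}

#' Simulate a reference single-cell atlas
#'
#' Draws a genes x cells sparse count matrix from the negative-binomial
#' model described by an [atlas_spec()], together with per-cell
#' annotations (cluster, sample, timepoint, reporter status, malignancy).
#' Marker gene indices are sampled across the genome so that planted
#' modules are not positionally confounded. One sample label is assigned
#' per timepoint, mimicking a sorted multi-timepoint collection.
#'
#' @param spec An [atlas_spec()].
#' @return A list of class `sim_atlas` with elements
#'   \describe{
#'     \item{counts}{sparse `dgCMatrix`, genes x cells, integer counts}
#'     \item{annotation}{data.frame with `cell_id`, `cluster`, `sample`,
#'       `timepoint`, `reporter`, `malignant`}
#'     \item{markers}{named list: planted marker gene ids per type}
#'     \item{spec}{the generating spec}
#'   }
#' @examples
#' atlas <- simulate_atlas(atlas_spec(n_cell_types = 3, cells_per_type = 50,
#'                                    n_genes = 300, markers_per_type = 10))
#' dim(atlas$counts)
#' @export
simulate_atlas <- function(spec) {
  if (!inherits(spec, "atlas_spec")) {
    stop("'spec' must be created with atlas_spec()", call. = FALSE)
  }
  n_genes <- spec$n_genes
  n_types <- spec$n_cell_types
  gene_ids <- sprintf("mg%0*d", nchar(n_genes), seq_len(n_genes))
  n_cells <- sum(spec$cells_per_type)
  cell_ids <- sprintf("cell-%0*d", nchar(n_cells), seq_len(n_cells))

  with_seed(spec$seed, {
    marker_idx <- sample.int(n_genes, n_types * spec$markers_per_type)
    markers <- split(gene_ids[marker_idx],
                     rep(spec$type_labels, each = spec$markers_per_type))
    markers <- markers[spec$type_labels]

    # per-cell library factor, expectation 1
    sdlog <- spec$library_size_scale
    size_factor <- stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)

    counts <- matrix(0, nrow = n_genes, ncol = n_cells)
    offset <- 0L
    for (t in seq_len(n_types)) {
      nc <- spec$cells_per_type[t]
      mu_gene <- rep(spec$baseline_mean, n_genes)
      mu_gene[match(markers[[t]], gene_ids)] <-
        spec$baseline_mean * spec$marker_fold_change
      cols <- offset + seq_len(nc)
      mu <- outer(mu_gene, size_factor[cols])
      counts[, cols] <- stats::rnbinom(n_genes * nc, mu = mu,
                                       size = spec$dispersion)
      offset <- offset + nc
    }
    dimnames(counts) <- list(gene_ids, cell_ids)

    cluster <- rep(spec$type_labels, times = spec$cells_per_type)
    timepoint <- unname(spec$timepoint_of_type[cluster])
    annotation <- data.frame(
      cell_id = cell_ids,
      cluster = cluster,
      sample = paste0("sample_", timepoint),
      timepoint = timepoint,
      reporter = "positive",
      malignant = "non_malignant",
      stringsAsFactors = FALSE
    )

    structure(list(
      counts = methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "generalMatrix"), "CsparseMatrix"),
      annotation = annotation,
      markers = markers,
      spec = spec
    ), class = "sim_atlas")
  })
}

#' @export
print.sim_atlas <- function(x, ...) {
  cat("Simulated atlas:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells;", length(x$markers), "cell types\n")
  invisible(x)
}

#' Simulate a cross-species ortholog map
#'
#' Assigns a unique target-species symbol to a fixed fraction of the
#' source genes (the one-to-one orthologs); the remainder stay unmapped.
#' The map is injective by construction — many-to-many resolution is a
#' policy of [map_orthologs()], not of the generator.
#'
#' @param genes Unique source-species gene identifiers.
#' @param frac_one_to_one Fraction of genes receiving a one-to-one
#'   ortholog, in `[0, 1]`.
#' @param seed Integer seed.
#' @return data.frame with columns `source_id`, `target_id`.
#' @export
simulate_ortholog_map <- function(genes, frac_one_to_one = 0.9, seed = 1L) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("'genes' must be non-empty", call. = FALSE)
  if (anyDuplicated(genes)) {
    stop("duplicate source identifiers in 'genes'", call. = FALSE)
  }
  if (!is.numeric(frac_one_to_one) || frac_one_to_one < 0 ||
      frac_one_to_one > 1) {
    stop("'frac_one_to_one' must be in [0, 1]", call. = FALSE)
  }
  n_map <- round(frac_one_to_one * length(genes))
  with_seed(seed, {
    mapped <- sort(sample(genes, n_map))
    data.frame(source_id = mapped,
               target_id = if (n_map > 0) paste0("H", toupper(mapped)) else character(0),
               stringsAsFactors = FALSE)
  })
}

#' Simulate labelled gene-family exclusion lists
#'
#' Samples disjoint gene sets standing in for the families typically
#' excluded before signature construction: cell-cycle/proliferation,
#' ribosome-biogenesis, mitochondrial and apoptosis-related genes.
#' Sampling is without replacement across families, so the sets are
#' disjoint; the family fractions must sum to less than 1.
#'
#' @param genes Gene identifiers to sample from.
#' @param families Named numeric vector of per-family fractions (names
#'   among `cell_cycle`, `ribosome`, `mitochondrial`, `apoptosis`).
#' @param seed Integer seed.
#' @return A named list with the four canonical families (empty character
#'   vectors for families not requested).
#' @export
simulate_gene_families <- function(genes,
                                   families = c(cell_cycle = 0.02,
                                                ribosome = 0.02,
                                                mitochondrial = 0.01,
                                                apoptosis = 0.01),
                                   seed = 1L) {
  genes <- as.character(genes)
  canonical <- c("cell_cycle", "ribosome", "mitochondrial", "apoptosis")
  if (length(families) > 0) {
    if (is.null(names(families)) || any(!nzchar(names(families)))) {
      stop("'families' must be a named vector of fractions", call. = FALSE)
    }
    if (!all(names(families) %in% canonical)) {
      stop("family names must be among: ",
           paste(canonical, collapse = ", "), call. = FALSE)
    }
    if (sum(families) >= 1) {
      stop("family fractions must sum to < 1", call. = FALSE)
    }
  }
  out <- stats::setNames(rep(list(character(0)), length(canonical)), canonical)
  with_seed(seed, {
    pool <- genes
    for (fam in names(families)) {
      n <- round(families[[fam]] * length(genes))
      picked <- if (n > 0) sample(pool, n) else character(0)
      out[[fam]] <- sort(picked)
      pool <- setdiff(pool, picked)
    }
  })
  out
}

#' Simulate ground-truth cell-type fractions
#'
#' Draws simplex columns for a set of mixtures: each mixture combines a
#' small random subset of cell types (by default two or three) in
#' comparable proportions (symmetric Dirichlet weights). This reflects
#' the downstream matching semantics, where a tumour cluster typically
#' resembles a handful of reference states at meaningful abundance.
#'
#' @param type_labels Cell-type labels (rows of the result).
#' @param n_mixtures Number of mixture columns.
#' @param k_range Candidate numbers of contributing types per mixture.
#' @param alpha Symmetric Dirichlet concentration for the weights of the
#'   contributing types; larger values give more even proportions.
#' @param seed Integer seed.
#' @return Matrix (types x mixtures); each column sums to 1.
#' @export
simulate_fraction_truth <- function(type_labels, n_mixtures = 40L,
                                    k_range = 2:3, alpha = 10, seed = 1L) {
  type_labels <- as.character(type_labels)
  if (length(type_labels) < max(k_range)) {
    stop("need at least max(k_range) cell types", call. = FALSE)
  }
  with_seed(seed, {
    truth <- matrix(0, nrow = length(type_labels), ncol = n_mixtures,
                    dimnames = list(type_labels,
                                    sprintf("mix%02d", seq_len(n_mixtures))))
    for (j in seq_len(n_mixtures)) {
      k <- if (length(k_range) == 1L) k_range else sample(k_range, 1L)
      types <- sample(type_labels, k)
      w <- stats::rgamma(k, shape = alpha, rate = 1)
      truth[types, j] <- w / sum(w)
    }
    truth
  })
}

#' Simulate tumour pseudobulk mixtures with known composition
#'
#' Forms each mixture as a convex combination of signature columns given
#' by a ground-truth fraction matrix, plus additive Gaussian noise scaled
#' per gene by the gene's mean signature expression and truncated at
#' zero. Noise-free mixtures are exact convex combinations.
#'
#' @param signature Genes x cell-types matrix (e.g. from
#'   [build_signature_matrix()] or [pseudobulk_cluster_means()]).
#' @param truth Cell-types x mixtures matrix of fractions; each column
#'   must sum to 1 and its row labels must be signature column labels.
#' @param noise_sd Noise level: per-gene noise standard deviation is
#'   `noise_sd` times the gene's mean signature value.
#' @param seed Integer seed.
#' @return A list of class `mixture_set` with elements `expr` (genes x
#'   mixtures), `truth` and `noise_sd`.
#' @export
simulate_mixtures <- function(signature, truth, noise_sd = 0.05, seed = 1L) {
  signature <- as_dense(signature)
  truth <- as.matrix(truth)
  check_positive_scalar(noise_sd, "noise_sd", strict = FALSE)
  unknown <- setdiff(rownames(truth), colnames(signature))
  if (length(unknown) > 0) {
    stop("unknown cell-type label(s) in truth: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  col_sums <- colSums(truth)
  if (any(abs(col_sums - 1) > 1e-8)) {
    stop("ground-truth columns must sum to 1", call. = FALSE)
  }
  S <- signature[, rownames(truth), drop = FALSE]
  clean <- S %*% truth
  with_seed(seed, {
    if (noise_sd > 0) {
      gene_scale <- rowMeans(S)
      noise <- matrix(stats::rnorm(length(clean)), nrow = nrow(clean)) *
        (noise_sd * gene_scale)
      expr <- pmax(clean + noise, 0)
    } else {
      expr <- clean
    }
    dimnames(expr) <- list(rownames(S), colnames(truth))
    structure(list(expr = expr, truth = truth, noise_sd = noise_sd),
              class = "mixture_set")
  })
}

#' @export
print.mixture_set <- function(x, ...) {
  cat("Mixture set:", nrow(x$expr), "genes x", ncol(x$expr),
      "mixtures (noise_sd =", x$noise_sd, ")\n")
  invisible(x)
}
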