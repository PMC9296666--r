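#' Rank cluster markers by minimum pairwise log fold change
#'
#' For each cluster and each of its candidate marker genes, computes the
#' log fold change against every other cluster separately and ranks the
#' genes by the minimum of those pairwise LFCs (descending). A gene that
#' is higher in the cluster than in *every* other cluster gets a
#' positive minimum and ranks above any gene that loses even one
#' pairwise comparison. Pairwise LFCs are differences of cluster mean
#' log-normalized expression (`mean_c - mean_c'`), the convention of
#' linear-model DE on log expression; this differs from the
#' [wilcoxon_de()] `avg_lfc`, which de-logs before averaging.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param labels Named vector mapping every cell to a cluster.
#' @param de_genes Named list: candidate gene ids per cluster (typically
#'   the retained genes of a DE table).
#' @return Named list of data.frames (`gene`, `min_pairwise_lfc`),
#'   sorted descending by `min_pairwise_lfc`.
#' @export
rank_markers_min_pairwise_lfc <- function(normalized, labels, de_genes) {
  cells <- colnames(normalized)
  if (!all(cells %in% names(labels))) {
    stop("every cell must be labelled", call. = FALSE)
  }
  labels <- as.character(labels[cells])
  clusters <- sort(unique(labels))
  bad <- setdiff(unlist(de_genes), rownames(normalized))
  if (length(bad) > 0) {
    stop("de_genes not in matrix: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  cluster_means <- pseudobulk_cluster_means(normalized,
                                            stats::setNames(labels, cells))

  out <- stats::setNames(vector("list", length(clusters)), clusters)
  for (cl in clusters) {
    genes <- intersect(de_genes[[cl]] %||% character(0), rownames(normalized))
    if (length(genes) == 0L) {
      out[[cl]] <- data.frame(gene = character(0),
                              min_pairwise_lfc = numeric(0))
      next
    }
    others <- setdiff(clusters, cl)
    lfc <- cluster_means[genes, cl] -
      cluster_means[genes, others, drop = FALSE]
    min_lfc <- apply(lfc, 1L, min)
    ord <- order(-min_lfc, genes)
    out[[cl]] <- data.frame(gene = genes[ord],
                            min_pairwise_lfc = unname(min_lfc[ord]),
                            stringsAsFactors = FALSE)
  }
  out
}

#' Drop clusters with too few cells
#'
#' Removes cells belonging to clusters smaller than `min_cells` (strict
#' `<`; a cluster of exactly `min_cells` cells is kept). Small unknown
#' clusters give unreliable signature columns and are discarded before
#' signature construction.
#'
#' @param labels Named vector mapping cells to clusters.
#' @param min_cells Minimum cluster size to keep (default 20).
#' @return The filtered label vector, with an attribute
#'   `dropped_clusters` naming the removed clusters.
#' @export
drop_small_clusters <- function(labels, min_cells = 20L) {
  check_positive_scalar(min_cells, "min_cells", integer = TRUE)
  sizes <- table(as.character(labels))
  dropped <- names(sizes)[sizes < min_cells]
  if (length(dropped) == length(sizes)) {
    stop("all clusters fall below min_cells = ", min_cells, call. = FALSE)
  }
  if (length(dropped) > 0) {
    message("dropping ", length(dropped), " cluster(s) with < ", min_cells,
            " cells: ", paste(dropped, collapse = ", "))
  }
  out <- labels[!(as.character(labels) %in% dropped)]
  attr(out, "dropped_clusters") <- dropped
  out
}

#' Remove excluded gene families from a gene list
#'
#' Drops every gene belonging to any of the exclusion families
#' (cell-cycle/proliferation, ribosome biogenesis, mitochondrial,
#' apoptosis), preserving the order of the remaining genes.
#'
#' @param genes Character vector of gene identifiers.
#' @param sets Named list of gene-identifier vectors (e.g. from
#'   [simulate_gene_families()] or read from file).
#' @return `genes` minus the union of all sets, original order kept.
#' @export
exclude_gene_families <- function(genes, sets) {
  excluded <- unique(unlist(sets, use.names = FALSE))
  genes[!(genes %in% excluded)]
}

#' Translate a matrix into the target species' gene namespace
#'
#' Renames rows via an ortholog map (`source_id` -> `target_id`). Rows
#' without a mapping are dropped. Under the default `one_to_one_only`
#' policy, any source gene sharing a target with another source is also
#' dropped; under `highest_expression`, the source with the highest row
#' mean among those sharing a target is retained. The retained map is
#' injective either way.
#'
#' @param x Genes x columns matrix with source-species rownames.
#' @param map data.frame with columns `source_id` and `target_id`.
#' @param policy Many-to-one resolution policy.
#' @return The matrix restricted to mapped rows, renamed to target
#'   symbols, with attribute `n_dropped` (rows lost to mapping).
#' @export
map_orthologs <- function(x, map,
                          policy = c("one_to_one_only", "highest_expression")) {
  policy <- match.arg(policy)
  if (!all(c("source_id", "target_id") %in% colnames(map))) {
    stop("'map' needs columns source_id and target_id", call. = FALSE)
  }
  if (anyDuplicated(map$source_id)) {
    stop("duplicate source_id entries in ortholog map", call. = FALSE)
  }
  dup_target <- map$target_id %in% map$target_id[duplicated(map$target_id)]
  if (any(dup_target)) {
    if (policy == "one_to_one_only") {
      map <- map[!dup_target, , drop = FALSE]
    } else {
      expr <- rowMeans(as_dense(x))[map$source_id]
      expr[is.na(expr)] <- -Inf
      keep <- unlist(lapply(split(seq_len(nrow(map)), map$target_id),
                            function(i) i[which.max(expr[i])]),
                     use.names = FALSE)
      map <- map[sort(keep), , drop = FALSE]
    }
  }
  idx <- match(rownames(x), map$source_id)
  keep <- !is.na(idx)
  if (!any(keep)) {
    stop("no matrix gene has an ortholog mapping", call. = FALSE)
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- map$target_id[idx[keep]]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Build the cell-type signature matrix
#'
#' Assembles the genes x cell-types matrix used as the deconvolution
#' basis: the gene universe is the union over clusters of retained DE
#' genes, minus the excluded gene families; values are the per-cluster
#' arithmetic means of (log) normalized expression restricted to that
#' universe; finally rows are translated to the target species' gene
#' namespace via the ortholog map.
#'
#' @param normalized Genes x cells normalized matrix (same cells/labels
#'   the markers were computed from).
#' @param labels Named vector mapping cells to clusters.
#' @param markers A `marker_table` from [wilcoxon_de()] (its `retained`
#'   rows define each cluster's DE genes).
#' @param exclusions Optional gene-family list for
#'   [exclude_gene_families()].
#' @param orthologs Optional ortholog map for [map_orthologs()].
#' @param ortholog_policy Passed to [map_orthologs()].
#' @return Genes x cell-types matrix of class `signature_matrix`.
#' @export
build_signature_matrix <- function(normalized, labels, markers,
                                   exclusions = NULL, orthologs = NULL,
                                   ortholog_policy = "one_to_one_only") {
  if (!inherits(markers, "marker_table")) {
    stop("'markers' must come from wilcoxon_de()", call. = FALSE)
  }
  universe <- unique(markers$gene[markers$retained])
  if (length(universe) == 0L) {
    stop("empty signature gene universe: no gene passed the DE filters",
         call. = FALSE)
  }
  if (!is.null(exclusions)) {
    universe <- exclude_gene_families(universe, exclusions)
    if (length(universe) == 0L) {
      stop("empty signature gene universe: gene-family exclusion removed all DE genes",
           call. = FALSE)
    }
  }
  means <- pseudobulk_cluster_means(normalized, labels)
  sig <- means[intersect(universe, rownames(means)), , drop = FALSE]
  if (!is.null(orthologs)) {
    sig <- map_orthologs(sig, orthologs, policy = ortholog_policy)
    if (nrow(sig) == 0L) {
      stop("empty signature gene universe: ortholog mapping removed all genes",
           call. = FALSE)
    }
  }
  class(sig) <- c("signature_matrix", class(sig))
  sig
}

#' Genes shared between a tumour profile and its matched reference type
#'
#' Scores how similar each signature gene's expression is between a
#' tumour pseudobulk profile and the matched reference cell type's
#' signature column: score = tumour value minus reference value. Genes
#' expressed above a floor in *both* profiles are ranked by ascending
#' absolute difference (most-shared first), with ties broken toward
#' higher shared magnitude (larger `min(tumour, reference)`), so that
#' genes that are high in both and nearly equal top the list.
#'
#' @param signature A signature matrix.
#' @param tumour_profile Named numeric vector on the signature's gene
#'   universe.
#' @param matched_type One of the signature's cell-type columns.
#' @param top_n Number of genes to return.
#' @param floor Expression floor: both values must exceed it (default
#'   0.5) for a gene to be rankable.
#' @return data.frame (`gene`, `tumour`, `reference`, `difference`),
#'   at most `top_n` rows.
#' @export
shared_signature_genes <- function(signature, tumour_profile, matched_type,
                                   top_n = 50L, floor = 0.5) {
  signature <- as_dense(signature)
  if (!matched_type %in% colnames(signature)) {
    stop("unknown cell type: ", matched_type, call. = FALSE)
  }
  common <- intersect(rownames(signature), names(tumour_profile))
  if (length(common) == 0L) {
    stop("tumour profile shares no genes with the signature", call. = FALSE)
  }
  ref <- signature[common, matched_type]
  tum <- tumour_profile[common]
  diff <- tum - ref
  eligible <- tum > floor & ref > floor
  ord <- order(abs(diff[eligible]), -pmin(tum[eligible], ref[eligible]))
  genes <- common[eligible][ord]
  genes <- utils::head(genes, top_n)
  data.frame(gene = genes,
             tumour = unname(tum[genes]),
             reference = unname(ref[genes]),
             difference = unname(diff[genes]),
             stringsAsFactors = FALSE)
}
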