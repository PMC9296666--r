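# Readers/writers for the plain-text interchange formats: 10x-style
# Matrix Market triplets with gene/barcode TSVs, and labelled TSV
# matrices (signature, fractions, ortholog maps, annotations).

#' Write a count matrix in 10x-style Matrix Market layout
#'
#' Writes `matrix.mtx` (1-based triplets), `genes.tsv` (one gene id per
#' line) and `barcodes.tsv` (one cell id per line) into a directory.
#'
#' @param counts Genes x cells matrix (sparse or dense) with dimnames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(as_dense(counts), sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a 10x-style Matrix Market count directory
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @return Sparse genes x cells `dgCMatrix` with dimnames.
#' @export
read_counts_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx in ", dir, call. = FALSE)
  m <- methods::as(methods::as(Matrix::readMM(mtx), "generalMatrix"),
                   "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
    stop("genes/barcodes do not match matrix dimensions", call. = FALSE)
  }
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a labelled matrix as TSV
#'
#' First column holds the row identifiers (named by `id_column`),
#' remaining columns the matrix columns.
#'
#' @param x Matrix with dimnames.
#' @param path Output file.
#' @param id_column Header of the identifier column (default "gene").
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(x, path, id_column = "gene") {
  x <- as_dense(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(x))
  write_tsv_file(df, path)
}

#' Read a labelled TSV matrix written by [write_matrix_tsv()]
#'
#' @param path Input file; the first column is taken as rownames.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write / read an ortholog map TSV
#'
#' Tab-separated with header `source_id` and `target_id`.
#'
#' @param map data.frame with columns `source_id`, `target_id`.
#' @param path File path.
#' @return `write_ortholog_map()` returns `path` invisibly;
#'   `read_ortholog_map()` the data.frame.
#' @export
write_ortholog_map <- function(map, path) {
  if (!all(c("source_id", "target_id") %in% colnames(map))) {
    stop("'map' needs columns source_id and target_id", call. = FALSE)
  }
  write_tsv_file(map[, c("source_id", "target_id")], path)
}

#' @rdname write_ortholog_map
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_id", "target_id") %in% colnames(df))) {
    stop("ortholog map file needs columns source_id and target_id",
         call. = FALSE)
  }
  df
}

#' Write a per-cell annotation table as TSV
#'
#' @param annotation data.frame with a `cell_id` column.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_annotation_tsv <- function(annotation, path) {
  if (!"cell_id" %in% colnames(annotation)) {
    stop("'annotation' needs a cell_id column", call. = FALSE)
  }
  write_tsv_file(annotation, path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
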