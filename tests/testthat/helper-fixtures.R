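# Deterministic toy count matrix exercising every QC rule, with cells
# designed on both sides of each boundary. 1190 nuclear genes + 10
# mitochondrial genes, 50 cells across two samples:
#   sample S1: 20 normal cells (1000..1019 detected genes), one empty
#     droplet (999 detected), one high-count doublet (1190 detected;
#     the per-sample median/SD rule flags it at doublet_k = 4)
#   sample S2: 25 normal cells (1001..1025 detected incl. 5 lowly
#     expressed mito genes), one boundary cell with exactly 1000
#     detected (kept), one high-mito cell (mito fraction 1/3), one
#     doublet (1150 detected)
make_qc_toy <- function() {
  genes <- c(sprintf("g%04d", seq_len(1190)), sprintf("mt-%02d", seq_len(10)))
  mito_rows <- 1191:1200

  cells <- list()
  add_cell <- function(name, sample, rows, values) {
    cells[[length(cells) + 1L]] <<- list(name = name, sample = sample,
                                         rows = rows, values = values)
  }
  for (i in seq_len(20)) {
    add_cell(sprintf("S1-n%02d", i), "S1", seq_len(999 + i), 1)
  }
  add_cell("S1-empty", "S1", seq_len(999), 1)
  add_cell("S1-dbl", "S1", seq_len(1190), 1)
  for (i in seq_len(25)) {
    add_cell(sprintf("S2-n%02d", i), "S2",
             c(seq_len(995 + i), mito_rows[1:5]), 1)
  }
  add_cell("S2-boundary", "S2", seq_len(1000), 1)
  add_cell("S2-mito", "S2", c(seq_len(1000), mito_rows),
           c(rep(1, 1000), rep(50, 10)))
  add_cell("S2-dbl", "S2", seq_len(1150), 2)

  i_idx <- unlist(lapply(cells, `[[`, "rows"))
  j_idx <- rep(seq_along(cells),
               vapply(cells, function(c) length(c$rows), 1L))
  x_val <- unlist(lapply(cells, function(c) rep_len(c$values, length(c$rows))))
  counts <- Matrix::sparseMatrix(
    i = i_idx, j = j_idx, x = x_val, dims = c(1200, length(cells)),
    dimnames = list(genes, vapply(cells, `[[`, "", "name"))
  )
  sample_of_cell <- stats::setNames(vapply(cells, `[[`, "", "sample"),
                                    colnames(counts))
  list(
    counts = counts,
    sample_of_cell = sample_of_cell,
    expected_removed = list(
      min_genes = "S1-empty",
      mito_fraction = "S2-mito",
      high_count_doublet = c("S1-dbl", "S2-dbl")
    )
  )
}

# Small normalized toy atlas reused by signature-level tests: builds a
# seeded atlas, normalizes, and returns labelled pieces.
make_toy_atlas <- function(n_types = 4, cells_per_type = 60, n_genes = 400,
                           markers_per_type = 20, fold = 8, seed = 42) {
  spec <- atlas_spec(n_cell_types = n_types, cells_per_type = cells_per_type,
                     n_genes = n_genes, markers_per_type = markers_per_type,
                     marker_fold_change = fold, seed = seed)
  atlas <- simulate_atlas(spec)
  norm <- normalize_log1p(atlas$counts)
  labels <- stats::setNames(atlas$annotation$cluster,
                            atlas$annotation$cell_id)
  list(atlas = atlas, norm = norm, labels = labels)
}
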