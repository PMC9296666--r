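test_that("QC removes exactly the designed cells, one rule each", {
  toy <- make_qc_toy()
  res <- qc_filter_cells(toy$counts, qc_thresholds(), toy$sample_of_cell)

  removed <- setdiff(colnames(toy$counts), colnames(res$counts))
  expect_setequal(removed, unlist(toy$expected_removed))

  # the boundary cell with exactly 1000 detected genes is retained
  expect_true("S2-boundary" %in% colnames(res$counts))

  rep_tab <- res$report
  get_n <- function(s, r) rep_tab$cells_removed[rep_tab$sample == s &
                                                  rep_tab$rule == r]
  expect_equal(get_n("S1", "min_genes"), 1)
  expect_equal(get_n("S1", "high_count_doublet"), 1)
  expect_equal(get_n("S2", "mito_fraction"), 1)
  expect_equal(get_n("S2", "high_count_doublet"), 1)
  expect_equal(get_n("S2", "min_genes"), 0)
  expect_equal(sum(rep_tab$cells_removed), 4)
})

test_that("QC filtering is a pure, stable function of its inputs", {
  toy <- make_qc_toy()
  r1 <- qc_filter_cells(toy$counts, qc_thresholds(), toy$sample_of_cell)
  r2 <- qc_filter_cells(toy$counts, qc_thresholds(), toy$sample_of_cell)
  expect_identical(as.matrix(r1$counts), as.matrix(r2$counts))
  expect_identical(r1$report, r2$report)

  # rerunning on the output removes nothing further by min-genes/mito
  r3 <- qc_filter_cells(r1$counts, qc_thresholds(), toy$sample_of_cell)
  tab <- r3$report
  expect_equal(sum(tab$cells_removed[tab$rule %in%
                                       c("min_genes", "mito_fraction")]), 0)
})

test_that("QC supports per-sample mito thresholds and errors on missing samples", {
  toy <- make_qc_toy()
  thr <- qc_thresholds(mito_max = c(S1 = 0.15, S2 = 0.05))
  res <- qc_filter_cells(toy$counts, thr, toy$sample_of_cell)
  expect_false("S2-mito" %in% colnames(res$counts))

  expect_error(qc_filter_cells(toy$counts, qc_thresholds(),
                               toy$sample_of_cell[-1]),
               "without sample")
  expect_error(qc_filter_cells(toy$counts,
                               qc_thresholds(mito_max = c(S1 = 0.1)),
                               toy$sample_of_cell),
               "S2")
})

test_that("the high-count rule flags cells beyond median + k*SD", {
  # one sample: 20 cells detecting 2900..3090 genes (median 2995,
  # SD ~57) plus one cell at 5100 - far beyond median + 4 SD
  n_genes <- 5200
  det <- c(seq(2900, 3090, by = 10), 5100)
  counts <- sapply(det, function(d) c(rep(1, d), rep(0, n_genes - d)))
  rownames(counts) <- sprintf("g%04d", seq_len(n_genes))
  colnames(counts) <- sprintf("c%02d", seq_along(det))
  res <- qc_filter_cells(counts, qc_thresholds(min_genes = 100),
                         stats::setNames(rep("s", ncol(counts)),
                                         colnames(counts)))
  expect_identical(setdiff(colnames(counts), colnames(res$counts)), "c21")
})

test_that("sex-linked genes are removed case-insensitively", {
  m <- matrix(1, 8, 2,
              dimnames = list(c("Xist", "TSIX", "eif2s3y", "Ddx3y", "Uty",
                                "Kdm5d", "Actb", "Gapdh"),
                              c("c1", "c2")))
  out <- remove_sex_genes(m)
  expect_equal(rownames(out), c("Actb", "Gapdh"))
  expect_equal(nrow(m) - nrow(out), 6)

  none <- m[7:8, , drop = FALSE]
  expect_identical(remove_sex_genes(none), none)
})

test_that("log1p normalization matches its defining formula", {
  counts <- matrix(0, 3, 2, dimnames = list(paste0("g", 1:3),
                                            paste0("c", 1:2)))
  counts[, 1] <- c(10, 9990, 0)
  counts[, 2] <- c(5, 5, 10)
  norm <- normalize_log1p(counts, scale_factor = 1e4)
  expect_equal(norm["g1", "c1"], log(11))   # 10/10000 * 10000 -> log1p(10)
  expect_equal(norm["g3", "c1"], 0)         # zero count stays zero

  # doubling the scale factor strictly increases every nonzero entry
  norm2 <- normalize_log1p(counts, scale_factor = 2e4)
  nz <- counts > 0
  expect_true(all(norm2[nz] > norm[nz]))

  # de-logged columns sum back to the scale factor
  expect_equal(colSums(expm1(norm)), c(c1 = 1e4, c2 = 1e4))

  bad <- counts
  bad[, 2] <- 0
  expect_error(normalize_log1p(bad), "c2")
})

test_that("sparse and dense normalization agree and preserve the zero pattern", {
  set.seed(1)
  dense <- matrix(rpois(600, 2), 30, 20,
                  dimnames = list(sprintf("g%02d", 1:30),
                                  sprintf("c%02d", 1:20)))
  sparse <- Matrix::Matrix(dense, sparse = TRUE)
  n_dense <- normalize_log1p(dense)
  n_sparse <- normalize_log1p(sparse)
  expect_equal(as.matrix(n_sparse), n_dense, ignore_attr = TRUE)
  expect_identical(as.matrix(n_sparse) == 0, dense == 0)
})

test_that("the G0/G1 gate relabels only upstream G1 cells", {
  norm <- matrix(0, 3, 4,
                 dimnames = list(c("Top2a", "Mki67", "Actb"),
                                 paste0("c", 1:4)))
  norm["Mki67", "c1"] <- 1.2   # cycling G1
  norm["Top2a", "c3"] <- 1.0   # exactly at the gate: strict >, so G0
  norm["Mki67", "c4"] <- 5     # S cell: passes through regardless
  phases <- c(c1 = "G1", c2 = "G1", c3 = "G1", c4 = "S")
  out <- gate_g0_g1(norm, phases)
  expect_equal(unname(out), c("G1", "G0", "G0", "S"))

  # case-insensitive gene match
  rownames(norm)[1:2] <- c("TOP2A", "MKI67")
  expect_equal(unname(gate_g0_g1(norm, phases)), c("G1", "G0", "G0", "S"))

  # missing gate genes: warn, treat as unexpressed
  expect_warning(out2 <- gate_g0_g1(norm[3, , drop = FALSE], phases),
                 "not found")
  expect_equal(unname(out2), c("G0", "G0", "G0", "S"))
})

test_that("pseudobulk means are arithmetic means, invariant to cell order", {
  m <- matrix(c(2, 0, 4, 6, 1, 5), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  labels <- c(c1 = "A", c2 = "A", c3 = "B")
  pb <- pseudobulk_cluster_means(m, labels)
  expect_equal(pb["g1", "A"], 3)       # mean(2, 4)
  expect_equal(pb[, "B"], c(g1 = 1, g2 = 5))  # single-cell cluster

  perm <- sample(colnames(m))
  pb2 <- pseudobulk_cluster_means(m[, perm], labels)
  expect_equal(pb, pb2)

  expect_error(pseudobulk_cluster_means(m, labels[1:2]), "unlabelled")
})

test_that("pseudobulk of a simulated type converges to its expected count profile", {
  spec <- atlas_spec(n_cell_types = 2, cells_per_type = 400, n_genes = 200,
                     markers_per_type = 10, marker_fold_change = 8,
                     library_size_scale = 0, seed = 21)
  atlas <- simulate_atlas(spec)
  counts <- as.matrix(atlas$counts)
  t1 <- atlas$annotation$cluster == spec$type_labels[1]
  mk <- atlas$markers[[1]]
  mu <- spec$baseline_mean * spec$marker_fold_change
  # NB variance mu + mu^2/size; per-gene empirical means within 4 SE,
  # their average within 3 SE/sqrt(n_markers)
  se <- sqrt((mu + mu^2 / spec$dispersion) / sum(t1))
  emp <- rowMeans(counts[mk, t1, drop = FALSE])
  expect_true(all(abs(emp - mu) < 4 * se))
  expect_lt(abs(mean(emp) - mu), 3 * se / sqrt(length(mk)))
  base <- rowMeans(counts[setdiff(rownames(counts), unlist(atlas$markers)),
                          t1, drop = FALSE])
  se_b <- sqrt((spec$baseline_mean + spec$baseline_mean^2 / spec$dispersion) /
                 sum(t1))
  expect_lt(max(abs(mean(base) - spec$baseline_mean)), 3 * se_b)
})
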