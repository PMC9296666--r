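toy <- make_toy_atlas()

test_that("planted markers are recovered by the DE filters", {
  de <- wilcoxon_de(toy$norm, toy$labels)
  for (t in names(toy$atlas$markers)) {
    kept <- de$gene[de$cluster == t & de$retained]
    recovered <- mean(toy$atlas$markers[[t]] %in% kept)
    expect_gte(recovered, 0.9)
  }
})

test_that("signature entries equal brute-force cluster means of normalized expression", {
  de <- wilcoxon_de(toy$norm, toy$labels)
  sig <- build_signature_matrix(toy$norm, toy$labels, de)
  bf <- oracle_cluster_means(toy$norm[rownames(sig), ],
                             unname(toy$labels[colnames(toy$norm)]))
  expect_equal(unclass(sig), bf[rownames(sig), colnames(sig)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(sig >= 0))
  expect_false(anyDuplicated(rownames(sig)) > 0)
})

test_that("minimum pairwise LFC ranking follows its defining arithmetic", {
  # one gene, three one-cell clusters with log-means A=3, B=1, C=2:
  # min pairwise LFC for A = min(3-1, 3-2) = 1
  m <- matrix(c(3, 1, 2), nrow = 1,
              dimnames = list("g1", c("c1", "c2", "c3")))
  labels <- c(c1 = "A", c2 = "B", c3 = "C")
  rk <- rank_markers_min_pairwise_lfc(m, labels, list(A = "g1"))
  expect_equal(rk$A$min_pairwise_lfc, 1)

  # a gene losing one pairwise comparison ranks below an all-winner
  m2 <- rbind(g1 = c(3, 1, 2), g2 = c(3, 1, 4))
  colnames(m2) <- names(labels)
  rk2 <- rank_markers_min_pairwise_lfc(m2, labels,
                                       list(A = c("g1", "g2")))
  expect_equal(rk2$A$gene, c("g1", "g2"))
  expect_lt(rk2$A$min_pairwise_lfc[2], 0)

  expect_equal(nrow(rank_markers_min_pairwise_lfc(m, labels,
                                                  list(A = character(0)))$A), 0)
})

test_that("planted markers top their own type's pairwise ranking", {
  de <- wilcoxon_de(toy$norm, toy$labels)
  de_genes <- split(de$gene[de$retained], de$cluster[de$retained])
  rk <- rank_markers_min_pairwise_lfc(toy$norm, toy$labels, de_genes)
  # brute-force recomputation of pairwise mean differences for one type
  t1 <- names(toy$atlas$markers)[1]
  means <- oracle_cluster_means(toy$norm, unname(toy$labels[colnames(toy$norm)]))
  g <- rk[[t1]]$gene[1]
  others <- setdiff(colnames(means), t1)
  expect_equal(rk[[t1]]$min_pairwise_lfc[1],
               min(means[g, t1] - means[g, others]))
  # markers dominate the top of the list
  top <- rk[[t1]]$gene[seq_len(10)]
  expect_gte(mean(top %in% toy$atlas$markers[[t1]]), 0.9)
})

test_that("small clusters are dropped with >= boundary kept", {
  labels <- stats::setNames(rep(c("A", "B", "C"), c(25, 20, 5)),
                            sprintf("c%02d", 1:50))
  expect_message(out <- drop_small_clusters(labels, 20), "C")
  expect_setequal(unique(out), c("A", "B"))
  expect_equal(attr(out, "dropped_clusters"), "C")
  expect_equal(length(drop_small_clusters(labels, 1)), 50)
  expect_error(drop_small_clusters(labels, 1000), "all clusters")
})

test_that("gene-family exclusion removes the union, preserving order", {
  genes <- c("a", "b", "c", "d", "e")
  sets <- list(cell_cycle = c("b", "d"), ribosome = c("d", "x"))
  expect_equal(exclude_gene_families(genes, sets), c("a", "c", "e"))
  expect_equal(exclude_gene_families(genes, list()), genes)
})

test_that("ortholog mapping renames, drops unmapped, and applies policy", {
  m <- matrix(1:8, nrow = 4,
              dimnames = list(c("g1", "g2", "g3", "g4"), c("A", "B")))
  full <- data.frame(source_id = paste0("g", 1:4),
                     target_id = paste0("H", 1:4))
  out <- map_orthologs(m, full)
  expect_equal(rownames(out), paste0("H", 1:4))
  expect_equal(unname(out[, "A"]), 1:4)

  partial <- full[1:3, ]
  out2 <- map_orthologs(m, partial)
  expect_equal(nrow(out2), 3)
  expect_equal(attr(out2, "n_dropped"), 1)

  shared <- data.frame(source_id = c("g1", "g2", "g3"),
                       target_id = c("H1", "H1", "H3"))
  out3 <- map_orthologs(m, shared)   # one_to_one_only: g1, g2 both dropped
  expect_equal(rownames(out3), "H3")

  out4 <- map_orthologs(m, shared, policy = "highest_expression")
  expect_setequal(rownames(out4), c("H1", "H3"))
  expect_equal(unname(out4["H1", ]), unname(m["g2", ]))  # higher row mean

  expect_error(map_orthologs(m, data.frame(source_id = c("g1", "g1"),
                                           target_id = c("H1", "H2"))),
               "duplicate")
  expect_error(map_orthologs(m, data.frame(source_id = "zz",
                                           target_id = "H9")),
               "no matrix gene")
})

test_that("exclusion-then-ortholog equals ortholog-then-exclusion", {
  de <- wilcoxon_de(toy$norm, toy$labels)
  genes <- rownames(toy$norm)
  fams <- simulate_gene_families(genes, c(cell_cycle = 0.05, ribosome = 0.05),
                                 seed = 2)
  omap <- simulate_ortholog_map(genes, 0.9, seed = 3)
  sig_a <- build_signature_matrix(toy$norm, toy$labels, de,
                                  exclusions = fams, orthologs = omap)
  # other order: map first, then exclude translated family genes
  sig_b <- build_signature_matrix(toy$norm, toy$labels, de,
                                  orthologs = omap)
  fams_t <- lapply(fams, function(s) {
    omap$target_id[match(s, omap$source_id)]
  })
  sig_b <- sig_b[setdiff(rownames(sig_b), unlist(fams_t)), , drop = FALSE]
  expect_equal(sort(rownames(sig_a)), sort(rownames(sig_b)))
  expect_equal(unclass(sig_a)[rownames(sig_b), ], unclass(sig_b),
               ignore_attr = TRUE)
})

test_that("signature construction honours exclusions and reports empty universes", {
  de <- wilcoxon_de(toy$norm, toy$labels)
  victim <- de$gene[de$retained][1]
  sig <- build_signature_matrix(toy$norm, toy$labels, de,
                                exclusions = list(cell_cycle = victim))
  expect_false(victim %in% rownames(sig))

  all_genes <- unique(de$gene[de$retained])
  expect_error(build_signature_matrix(toy$norm, toy$labels, de,
                                      exclusions = list(cc = all_genes)),
               "exclusion")
  de_none <- de
  de_none$retained <- FALSE
  expect_error(build_signature_matrix(toy$norm, toy$labels, de_none),
               "no gene passed")
})

test_that("shared-gene scoring ranks high co-expressed, similar genes first", {
  sig <- matrix(c(3, 2.5, 0.2, 1.0, 4.0,
                  1, 1, 1, 1, 1), ncol = 2,
                dimnames = list(paste0("g", 1:5), c("match", "other")))
  tumour <- c(g1 = 3.1, g2 = 0.1, g3 = 2.0, g4 = 1.4, g5 = 3.0)
  res <- shared_signature_genes(sig, tumour, "match", top_n = 5, floor = 0.5)
  # eligible: both > 0.5 -> g1 (|diff| 0.1), g4 (0.4), g5 (1.0)
  expect_equal(res$gene, c("g1", "g4", "g5"))
  # brute-force sort oracle
  both_high <- names(tumour)[tumour > 0.5 & sig[, "match"] > 0.5]
  ord <- both_high[order(abs(tumour[both_high] - sig[both_high, "match"]))]
  expect_equal(res$gene, ord)
  expect_equal(res$difference, unname(tumour[res$gene] - sig[res$gene, "match"]))

  # identical profile: zero differences, ranking by shared magnitude
  same <- sig[, "match"]
  res2 <- shared_signature_genes(sig, same, "match", top_n = 5)
  expect_true(all(res2$difference == 0))
  expect_equal(res2$gene[1], "g5")   # highest shared expression first

  # gene absent in tumour is ineligible
  expect_false("g2" %in% res$gene)
  expect_error(shared_signature_genes(sig, tumour, "nope"), "unknown")
})
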