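test_that("filter_cells applies detected-gene and total-count thresholds", {
  # 3 cells with totals 10, 50, 100 and varying detected genes
  m <- toy_counts(cbind(c(10, 0, 0), c(25, 25, 0), c(40, 30, 30)))
  expect_equal(cell_ids(filter_cells(m, min_genes = 0, min_total_umi = 60)), "c3")
  expect_equal(cell_ids(filter_cells(m, min_genes = 2, min_total_umi = 0)),
               c("c2", "c3"))
  expect_equal(as.matrix(counts(filter_cells(m, 0, 0))), as.matrix(counts(m)))
  # a cell with 150 detected genes fails a 200-gene floor
  big <- toy_counts(cbind(c(rep(1, 150), rep(0, 100)), rep(1, 250)))
  expect_equal(cell_ids(filter_cells(big, min_genes = 200)), "c2")
  expect_error(filter_cells(m, min_genes = 4), class = "sctfidf_empty_result_error")
})

test_that("MAD cell outlier removal drops far-from-centroid cells only", {
  # 5 cells: four identical, one wildly different -> distances (d,d,d,d,D)
  base <- matrix(2, 20, 4)
  out <- matrix(c(rep(0, 10), rep(60, 10)), 20, 1)
  m <- toy_counts(cbind(base, out))
  kept <- remove_cell_outliers_mad(m, k_mad = 3)
  expect_equal(cell_ids(kept), paste0("c", 1:4))
  # all distances equal (symmetric simplex) -> MAD 0, none strictly above
  # the median -> identity
  m2 <- toy_counts(diag(3))
  expect_equal(cell_ids(remove_cell_outliers_mad(m2, k_mad = 3)), cell_ids(m2))
  # k_mad = Inf is the identity
  expect_equal(cell_ids(remove_cell_outliers_mad(m, k_mad = Inf)), cell_ids(m))
  # groups smaller than 3 pass through with a warning
  lab <- stats::setNames(c("a", "a", "b", "b", "b"), cell_ids(m))
  expect_warning(remove_cell_outliers_mad(m, labels = lab, k_mad = 3),
                 "fewer than 3")
})

test_that("filter_genes applies the min-total and one-sided MAD rules", {
  m <- toy_counts(cbind(c(0, 2, 5), c(0, 3, 5)))
  expect_equal(gene_ids(filter_genes(m, min_total = 1, k_mad = Inf)),
               c("g2", "g3"))
  expect_equal(gene_ids(filter_genes(m, min_total = 0, k_mad = Inf)),
               gene_ids(m))
  # totals (10,10,10,10,1e6): MAD of log-totals is 0 -> the high gene goes
  hi <- toy_counts(matrix(c(rep(10, 4), 1e6), 5, 1))
  expect_equal(gene_ids(filter_genes(hi, min_total = 0, k_mad = 3)),
               paste0("g", 1:4))
  expect_error(filter_genes(m, min_total = 100), class = "sctfidf_empty_result_error")
})

test_that("exclude_genes removes named genes and warns on unknown names", {
  m <- toy_counts(matrix(1:6, 3, 2))
  rownames(m$values) <- c("INS", "GCG", "ACTB")
  expect_equal(gene_ids(exclude_genes(m, c("INS", "GCG"))), "ACTB")
  expect_equal(gene_ids(exclude_genes(m, character(0))), c("INS", "GCG", "ACTB"))
  expect_warning(out <- exclude_genes(m, "NOPE"), "NOPE")
  expect_equal(gene_ids(out), c("INS", "GCG", "ACTB"))
})

test_that("QC operations return submatrices and are idempotent", {
  mix <- small_mix(seed = 4, cells_per_type = c(40, 40), n_genes = 400)
  m <- mix$matrix
  f1 <- filter_cells(m, min_genes = 50)
  expect_true(all(cell_ids(f1) %in% cell_ids(m)))
  expect_equal(as.matrix(counts(m))[, cell_ids(f1)], as.matrix(counts(f1)))
  expect_equal(cell_ids(filter_cells(f1, min_genes = 50)), cell_ids(f1))

  g1 <- filter_genes(m, min_total = 1, k_mad = 3)
  g2 <- filter_genes(g1, min_total = 1, k_mad = 3)
  expect_equal(gene_ids(g2), gene_ids(g1))

  o1 <- remove_cell_outliers_mad(m, labels = mix$truth, k_mad = 3)
  o2 <- remove_cell_outliers_mad(o1, labels = mix$truth, k_mad = 3)
  expect_equal(cell_ids(o2), cell_ids(o1))
})
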