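test_that("compute_tf normalizes by the per-cell maximum", {
  m <- toy_counts(matrix(c(2, 8, 4), 3, 1))
  expect_equal(as.numeric(compute_tf(m)), c(0.25, 1, 0.5))
  # all counts equal -> all TF = 1; zero-count cell rejected by name
  expect_equal(as.numeric(compute_tf(toy_counts(matrix(3, 2, 1)))), c(1, 1))
  bad <- toy_counts(cbind(c(1, 2), c(0, 0)))
  expect_error(compute_tf(bad), "c2", class = "sctfidf_value_error")
})

test_that("compute_idf follows log2(N/n_i) with zero for undetected genes", {
  # 4 cells; g1 in all, g2 in 1 of 4, g3 in none
  m <- toy_counts(cbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(1, 0, 0)))
  idf <- compute_idf(m)
  expect_equal(unname(idf), c(0, 2, 0))
  # N = 1000, n_i = 10
  big <- count_matrix(matrix(c(rep(1, 10), rep(0, 990)), 1, 1000),
                      "g1", paste0("c", 1:1000))
  expect_equal(unname(compute_idf(big)), log2(100))
})

test_that("compute_tfidf equals the brute-force per-entry oracle", {
  mix <- small_mix(seed = 2, cells_per_type = c(10, 10), n_genes = 60)
  t <- compute_tfidf(mix$matrix)
  expect_equal(as.matrix(t$scores), naive_tfidf(counts(mix$matrix)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # zero counts always give zero scores
  expect_true(all(as.matrix(t$scores)[as.matrix(counts(mix$matrix)) == 0] == 0))
  # per cell, max TF is exactly 1
  tf <- compute_tf(mix$matrix)
  expect_equal(unname(apply(as.matrix(tf), 2, max)), rep(1, ncol(tf)))
})

test_that("TF is scale-invariant per cell and IDF depends only on detection", {
  mix <- small_mix(seed = 3, cells_per_type = c(8, 8), n_genes = 50)
  m <- mix$matrix
  tf1 <- as.matrix(compute_tf(m))
  scaled <- counts(m)
  scaled[, 3] <- scaled[, 3] * 7
  m2 <- count_matrix(scaled, gene_ids(m), cell_ids(m))
  expect_equal(as.matrix(compute_tf(m2)), tf1, tolerance = 1e-12)
  expect_equal(compute_idf(m2), compute_idf(m))
  # permuting cells permutes nothing in IDF
  perm <- sample(ncol(counts(m)))
  expect_equal(compute_idf(m[, perm]), compute_idf(m))
})

test_that("select_genes_top separates a bimodal mean distribution and caps by detection", {
  # synthetic TfidfMatrix: 100 genes with mean ~0.01, 50 with mean ~1.0
  set.seed(42)
  lo <- matrix(abs(rnorm(100 * 40, 0.01, 0.002)), 100, 40)
  hi <- matrix(abs(rnorm(50 * 40, 1.0, 0.05)), 50, 40)
  sc <- rbind(lo, hi)
  rownames(sc) <- paste0("g", 1:150)
  t <- structure(list(scores = Matrix::Matrix(sc, sparse = TRUE),
                      idf = rep(1, 150), n_detect = c(rep(5, 100), rep(30, 50)),
                      gene_ids = rownames(sc), cell_ids = paste0("c", 1:40)),
                 class = "TfidfMatrix")
  sel <- select_genes_top(t, seed = 1)
  expect_setequal(sel$selected_gene_ids, paste0("g", 101:150))
  # cap: rank by detection count
  t2 <- t
  t2$n_detect <- c(rep(5, 100), 50:1)
  sel2 <- select_genes_top(t2, max_genes = 10, seed = 1)
  expect_setequal(sel2$selected_gene_ids, paste0("g", 101:110))
  # Inf cap never applies
  sel3 <- select_genes_top(t, max_genes = Inf, seed = 1)
  expect_length(sel3$selected_gene_ids, 50)
  # degenerate input
  tbad <- t
  tbad$scores <- Matrix::Matrix(matrix(1, 150, 40), sparse = TRUE)
  expect_error(select_genes_top(tbad, seed = 1), class = "sctfidf_value_error")
})

test_that("select_genes_var ranks by residual from the log-log CV trend", {
  mix <- small_mix(seed = 5, cells_per_type = c(30, 30), n_genes = 300)
  t <- compute_tfidf(mix$matrix)
  eligible <- sum(Matrix::rowMeans(t$scores) > 0 &
                    apply(as.matrix(t$scores), 1, stats::sd) > 0)
  sel <- select_genes_var(t, keep_fraction = 0.30)
  expect_length(sel$selected_gene_ids, floor(eligible * 0.30))
  sel_all <- select_genes_var(t, keep_fraction = 1.0)
  expect_length(sel_all$selected_gene_ids, eligible)
  # every selected gene has residual >= every unselected eligible gene
  dg <- sel$diagnostics
  r_sel <- min(dg$residual[dg$selected], na.rm = TRUE)
  r_un <- suppressWarnings(max(dg$residual[!dg$selected & !is.na(dg$residual)],
                               na.rm = TRUE))
  expect_gte(r_sel, r_un - 1e-12)
})

test_that("gene selections are stable under cell reordering", {
  mix <- small_mix(seed = 6, cells_per_type = c(25, 25), n_genes = 200)
  t1 <- compute_tfidf(mix$matrix)
  perm <- sample(ncol(counts(mix$matrix)))
  t2 <- compute_tfidf(mix$matrix[, perm])
  expect_setequal(select_genes_top(t1, seed = 2)$selected_gene_ids,
                  select_genes_top(t2, seed = 2)$selected_gene_ids)
  expect_setequal(select_genes_var(t1)$selected_gene_ids,
                  select_genes_var(t2)$selected_gene_ids)
})

test_that("binarize thresholds at multiplier x mean of per-cell nonzero scores", {
  t <- structure(list(scores = Matrix::Matrix(matrix(c(0.2, 0.4, 0, 0.001, 1, 0),
                                                     3, 2), sparse = TRUE),
                      idf = rep(1, 3), n_detect = c(2, 2, 0),
                      gene_ids = paste0("g", 1:3), cell_ids = c("c1", "c2")),
                 class = "TfidfMatrix")
  b <- binarize(t, multiplier = 0.1)
  expect_equal(unname(b$cutoff_used), c(0.03, 0.05005))
  expect_equal(unname(as.matrix(b$signatures)),
               cbind(c(1, 1, 0), c(0, 1, 0)))
  # multiplier 0: detection mask
  b0 <- binarize(t, multiplier = 0)
  expect_equal(unname(as.matrix(b0$signatures) > 0),
               unname(as.matrix(t$scores) > 0))
  # cell with no nonzero score is rejected
  tbad <- t
  tbad$scores[, 2] <- 0
  expect_error(binarize(tbad), "c2", class = "sctfidf_value_error")
})
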