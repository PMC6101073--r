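# Shared fixtures and independent oracles.

# small hand-sized count matrix
toy_counts <- function(values, unit = "umi") {
  values <- as.matrix(values)
  count_matrix(values,
               paste0("g", seq_len(nrow(values))),
               paste0("c", seq_len(ncol(values))),
               unit = unit)
}

# reduced-size mixture for fast unit tests (full-size fixtures are built in
# test-acceptance.R at the sizes the criteria state)
small_mix <- function(seed = 1, cells_per_type = c(60, 60), similarity = 0,
                      n_genes = 600, n_markers_per_type = 10, ...) {
  generate_mixture(mixture_spec(cells_per_type = cells_per_type,
                                n_genes = n_genes, similarity = similarity,
                                n_markers_per_type = n_markers_per_type,
                                seed = seed, ...))
}

# naive double-loop distance oracle, deliberately independent of
# pairwise_distances()
naive_pairwise <- function(m, metric) {
  n <- ncol(m)
  d <- matrix(0, n, n)
  f <- switch(metric,
    euclidean = function(a, b) sqrt(sum((a - b)^2)),
    pearson = pearson_distance,
    cosine = cosine_dissimilarity,
    jaccard = jaccard_distance)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    d[i, j] <- f(m[, i], m[, j])
  d
}

# brute-force TF-IDF oracle: literal per-entry evaluation of the formulas
naive_tfidf <- function(counts) {
  counts <- as.matrix(counts)
  N <- ncol(counts)
  out <- matrix(0, nrow(counts), N)
  for (j in seq_len(N)) {
    mx <- max(counts[, j])
    for (i in seq_len(nrow(counts))) {
      n_i <- sum(counts[i, ] > 0)
      idf <- if (n_i > 0) log2(N / n_i) else 0
      out[i, j] <- (counts[i, j] / mx) * idf
    }
  }
  out
}

# write a MatrixMarket coordinate file by hand (independent of Matrix pkg)
write_mtx_text <- function(path, nrow, ncol, triplets) {
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(nrow, ncol, nrow(triplets)))
  for (r in seq_len(nrow(triplets)))
    lines <- c(lines, paste(triplets[r, 1], triplets[r, 2], triplets[r, 3]))
  writeLines(lines, path)
}

make_10x_dir <- function(dir, nrow = 3, ncol = 2,
                         triplets = cbind(c(1, 2), c(1, 2), c(5, 3)),
                         genes = NULL, barcodes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_text(file.path(dir, "matrix.mtx"), nrow, ncol, triplets)
  if (is.null(genes)) genes <- paste0("ENSG", seq_len(nrow), "\tGENE", seq_len(nrow))
  writeLines(genes, file.path(dir, "genes.tsv"))
  if (is.null(barcodes)) barcodes <- paste0("BC", seq_len(ncol))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}
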