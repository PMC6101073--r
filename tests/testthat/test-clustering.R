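test_that("kmeans handles k = 1, k = n, and separates distant clouds", {
  set.seed(1)
  m <- cbind(matrix(rnorm(40, 0, 0.1), 2), matrix(rnorm(40, 10, 0.1), 2))
  colnames(m) <- paste0("c", 1:40)
  a1 <- kmeans_cluster(m, 1, seed = 3)
  expect_equal(a1$k, 1)
  a2 <- kmeans_cluster(m, 2, seed = 3)
  expect_equal(a2$k, 2)
  expect_length(unique(a2$labels[1:20]), 1)
  expect_length(unique(a2$labels[21:40]), 1)
  an <- kmeans_cluster(m, 40, seed = 3)
  expect_equal(an$k, 40)
  expect_error(kmeans_cluster(m, 41, seed = 3), class = "sctfidf_value_error")
  # labels are 0-based contiguous, ordered by first occurrence
  expect_equal(a2$labels[[1]], 0L)
  expect_setequal(unique(a2$labels), 0:1)
})

test_that("spherical k-means is scale-invariant and splits orthogonal bundles", {
  set.seed(2)
  b1 <- matrix(abs(rnorm(30, 1, 0.05)), 3) * c(1, 0.05, 0.05)
  b2 <- matrix(abs(rnorm(30, 1, 0.05)), 3) * c(0.05, 1, 0.05)
  m <- cbind(b1, b2)
  colnames(m) <- paste0("c", 1:20)
  a <- spherical_kmeans(m, 2, seed = 1)
  expect_equal(a$k, 2)
  expect_length(unique(a$labels[1:10]), 1)
  expect_length(unique(a$labels[11:20]), 1)
  # positive rescaling of cells leaves assignments unchanged
  m2 <- m %*% diag(runif(20, 0.1, 10))
  colnames(m2) <- colnames(m)
  expect_equal(spherical_kmeans(m2, 2, seed = 1)$labels, a$labels)
  expect_equal(spherical_kmeans(m, 1, seed = 1)$k, 1)
  expect_error(spherical_kmeans(cbind(m, 0), 2, seed = 1),
               class = "sctfidf_value_error")
})

test_that("EM-GMM recovers well-separated Gaussians with monotone log-likelihood", {
  set.seed(3)
  m <- cbind(matrix(rnorm(2 * 200, 0, 1), 2), matrix(rnorm(2 * 200, 10, 1), 2))
  colnames(m) <- paste0("c", 1:400)
  truth <- rep(0:1, each = 200)
  a <- gmm_em(m, 2, seed = 5)
  expect_equal(a$k, 2)
  agree <- max(mean(a$labels == truth), mean(a$labels == 1 - truth))
  expect_gte(agree, 0.99)
  ll <- a$params$loglik
  expect_true(all(diff(ll) > -1e-6))
  expect_equal(gmm_em(m, 1, seed = 5)$k, 1)
})

test_that("Ward hierarchical clustering recovers separated groups and checks symmetry", {
  x <- matrix(c(0, 0.1, 5, 5.1, 10, 10.1), 1)
  colnames(x) <- paste0("c", 1:6)
  d <- pairwise_distances(x, "euclidean")
  a <- hierarchical_ward(d, 3)
  expect_equal(unname(a$labels), c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_equal(hierarchical_ward(d, 6)$k, 6)
  bad <- d$d; bad[1, 2] <- 99
  expect_error(hierarchical_ward(bad, 2), class = "sctfidf_value_error")
})

test_that("Ward merge heights match a hand-rolled Lance-Williams trace", {
  # independent oracle: naive Ward (ward.D2 recurrence) on 4 points
  set.seed(11)
  x <- matrix(rnorm(8), 2, 4)
  colnames(x) <- paste0("c", 1:4)
  D <- as.matrix(stats::dist(t(x)))
  naive_ward_heights <- function(D) {
    n <- nrow(D)
    active <- as.list(seq_len(n))
    sizes <- rep(1, n)
    D2 <- D^2
    heights <- numeric(0)
    while (length(active) > 1) {
      k <- length(active)
      best <- c(Inf, 0, 0)
      for (i in 1:(k - 1)) for (j in (i + 1):k)
        if (D2[i, j] < best[1]) best <- c(D2[i, j], i, j)
      i <- best[2]; j <- best[3]
      heights <- c(heights, sqrt(best[1]))
      ni <- sizes[i]; nj <- sizes[j]
      newrow <- vapply(seq_len(k), function(l) {
        if (l == i || l == j) return(NA_real_)
        nl <- sizes[l]
        ((ni + nl) * D2[i, l] + (nj + nl) * D2[j, l] - nl * D2[i, j]) /
          (ni + nj + nl)
      }, 0)
      keep <- setdiff(seq_len(k), c(i, j))
      D2 <- rbind(cbind(D2[keep, keep, drop = FALSE], newrow[keep]),
                  c(newrow[keep], 0))
      sizes <- c(sizes[keep], ni + nj)
      active <- c(active[keep], list(unlist(active[c(i, j)])))
    }
    heights
  }
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  expect_equal(hc$height, naive_ward_heights(D), tolerance = 1e-10)
})

test_that("build_cell_graph scales distances and thresholds edges", {
  x <- matrix(c(0, 1, 3, 10), 1)
  colnames(x) <- paste0("c", 1:4)
  d <- pairwise_distances(x, "euclidean")
  g <- build_cell_graph(d, cutoff = 0.01)
  w <- igraph::E(g$graph)$weight
  expect_true(all(w > 0 & w <= 1))
  # the minimum-distance pair (scaled 0) is never an edge when cutoff > 0
  ends <- igraph::as_edgelist(g$graph)
  expect_false(any(ends[, 1] == "c1" & ends[, 2] == "c2"))
  # degenerate scaling rejected
  same <- pairwise_distances(matrix(c(0, 1, 0, 1), 1, 4,
                                    dimnames = list(NULL, paste0("c", 1:4))),
                             "euclidean")
  same$d[] <- 1; diag(same$d) <- 0
  expect_error(build_cell_graph(same), class = "sctfidf_value_error")
  # 3 cells: scaled distances are (0, 1, 0.75); only the 0.75 pair survives
  # (min pair below cutoff, max pair would carry weight 0)
  x3 <- matrix(c(0, 1, 5), 1, dimnames = list(NULL, paste0("c", 1:3)))
  g3 <- build_cell_graph(pairwise_distances(x3, "euclidean"), cutoff = 0.01)
  expect_equal(igraph::ecount(g3$graph), 1)
})

test_that("graph clustering finds planted communities and respects components", {
  # two 6-cliques joined by one light edge
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(6)
  g <- igraph::add_edges(g, c(1, 7))
  igraph::E(g)$weight <- c(rep(1, 30), 0.05)
  igraph::V(g)$name <- paste0("c", 1:12)
  cg <- structure(list(graph = g, metric = "test", cell_ids = paste0("c", 1:12)),
                  class = "CellGraph")
  for (alg in c("louvain", "greedy")) {
    a <- cluster_graph(cg, alg, seed = 1)
    expect_equal(a$k, 2)
    expect_length(unique(a$labels[1:6]), 1)
    expect_length(unique(a$labels[7:12]), 1)
    expect_gte(a$params$modularity,
               igraph::modularity(g, rep(1, 12), weights = igraph::E(g)$weight))
  }
  # single clique -> one community
  g1 <- igraph::make_full_graph(5)
  igraph::E(g1)$weight <- 1
  igraph::V(g1)$name <- paste0("c", 1:5)
  cg1 <- structure(list(graph = g1, metric = "test", cell_ids = paste0("c", 1:5)),
                   class = "CellGraph")
  expect_equal(cluster_graph(cg1, "louvain", seed = 1)$k, 1)
  # disconnected components are never merged
  g2 <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  igraph::E(g2)$weight <- 1
  igraph::V(g2)$name <- paste0("c", 1:8)
  cg2 <- structure(list(graph = g2, metric = "test", cell_ids = paste0("c", 1:8)),
                   class = "CellGraph")
  for (alg in c("louvain", "greedy")) {
    a2 <- cluster_graph(cg2, alg, seed = 1)
    expect_length(intersect(unique(a2$labels[1:4]), unique(a2$labels[5:8])), 0)
  }
})

test_that("back-ends are deterministic given input and seed", {
  mix <- small_mix(seed = 8, cells_per_type = c(30, 30), n_genes = 300)
  L <- log_transform(mix$matrix)
  expect_equal(kmeans_cluster(L, 3, seed = 9)$labels,
               kmeans_cluster(L, 3, seed = 9)$labels)
  expect_equal(spherical_kmeans(L, 3, seed = 9)$labels,
               spherical_kmeans(L, 3, seed = 9)$labels)
  p <- pca_front(L, 5)
  expect_equal(gmm_em(p, 2, seed = 9)$labels, gmm_em(p, 2, seed = 9)$labels)
  expect_equal(run_method("TF-IDF_Bin_Louvain_C", mix$matrix, k = 2, seed = 4)$labels,
               run_method("TF-IDF_Bin_Louvain_C", mix$matrix, k = 2, seed = 4)$labels)
})

test_that("recursive_partition honours identity cases and enforces min_k", {
  mix <- generate_nested_mixture(cells_per_type = c(60, 60, 60), n_genes = 800,
                                 n_unique_pair = 8, seed = 3)
  pipe <- function(sub) {
    b <- binarize(compute_tfidf(sub))
    d <- pairwise_distances(as.matrix(b$signatures), "cosine")
    list(assignment = cluster_graph(build_cell_graph(d), "louvain", seed = 3),
         dist = d)
  }
  top <- pipe(mix$matrix)
  # identity: base already has k >= min_k
  same <- recursive_partition(mix$matrix, pipe, base = top$assignment,
                              dist = top$dist, min_k = 1,
                              silhouette_threshold = 0.25)
  expect_equal(same$labels, stats::setNames(top$assignment$labels,
                                            names(same$labels)))
  # identity: threshold -1, nothing can be below
  same2 <- recursive_partition(mix$matrix, pipe, base = top$assignment,
                               dist = top$dist, min_k = top$assignment$k,
                               silhouette_threshold = -1)
  expect_equal(same2$k, top$assignment$k)
  # enforcing min_k splits the merged pair and never decreases k
  ref <- recursive_partition(mix$matrix, pipe, base = top$assignment,
                             dist = top$dist, min_k = 3,
                             silhouette_threshold = 0.25)
  expect_gte(ref$k, 3)
  expect_gte(ref$k, top$assignment$k)
})
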