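#' Log transform of counts
#'
#' Elementwise log2(x + 1).
#'
#' @param m a `CountMatrix` or numeric matrix.
#' @return Dense numeric matrix, genes x cells.
#' @export
log_transform <- function(m) {
  v <- if (inherits(m, "CountMatrix")) counts(m) else m
  as.matrix(log2(v + 1))
}

#' PCA front-end
#'
#' Projects cells onto the top principal axes of the (centered, unscaled)
#' gene dimension.
#'
#' @param m numeric matrix, features x cells.
#' @param n_components number of principal components (default 10).
#' @return Matrix of scores, n_components x cells.
#' @export
pca_front <- function(m, n_components = 10) {
  X <- t(as.matrix(m))
  if (n_components > min(dim(X)))
    stop_value("n_components (", n_components, ") exceeds min(dim) = ", min(dim(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (n_components > ncol(pc$x))
    stop_value("n_components (", n_components, ") exceeds available components (",
               ncol(pc$x), ")")
  t(pc$x[, seq_len(n_components), drop = FALSE])
}

#' 2-D tSNE front-end
#'
#' Barnes-Hut t-SNE (via Rtsne) of the cells, seeded for determinism. The
#' perplexity is shrunk automatically on small inputs (Rtsne requires
#' 3 * perplexity < n - 1).
#'
#' @param m numeric matrix, features x cells.
#' @param perplexity tSNE perplexity (default 30).
#' @param seed RNG seed.
#' @return Matrix 2 x cells.
#' @export
tsne_front <- function(m, perplexity = 30, seed = 1) {
  X <- t(as.matrix(m))
  n <- nrow(X)
  px <- min(perplexity, floor((n - 1) / 3) - 1)
  if (px < 1) stop_value("too few cells for tSNE (n = ", n, ")")
  if (px < perplexity)
    message("perplexity reduced to ", px, " for n = ", n, " cells")
  emb <- with_seed(seed,
                   Rtsne::Rtsne(X, dims = 2, perplexity = px,
                                check_duplicates = FALSE, verbose = FALSE))
  out <- t(emb$Y)
  colnames(out) <- rownames(X)
  out
}

# ---------------------------------------------------------------------------
# Method registry: every non-Seurat row of the comparison. `selected` marks
# the 26 methods retained after the 2-class screen (8 of the 34 were
# eliminated for consistently lower accuracy).
.method_registry <- local({
  entry <- function(front, algo, metric = NA_character_, selected = TRUE)
    list(front = front, algo = algo, metric = metric, selected = selected)
  list(
    Log_Kmeans          = entry("log",      "kmeans", selected = FALSE),
    Log_PCA_Kmeans      = entry("log_pca",  "kmeans"),
    tSNE_Kmeans         = entry("tsne",     "kmeans"),
    Log_PCA_GMM         = entry("log_pca",  "gmm"),
    Log_PCA_sKmeans     = entry("log_pca",  "skmeans", selected = FALSE),
    Log_PCA_HC_E        = entry("log_pca",  "hc", "euclidean"),
    Log_PCA_HC_P        = entry("log_pca",  "hc", "pearson"),
    tSNE_HC_E           = entry("tsne",     "hc", "euclidean"),
    tSNE_HC_P           = entry("tsne",     "hc", "pearson", selected = FALSE),
    Log_Louvain_E       = entry("log",      "louvain", "euclidean"),
    `TF-IDF_Top_GMM`    = entry("tfidf_top", "gmm", selected = FALSE),
    `TF-IDF_Var_GMM`    = entry("tfidf_var", "gmm", selected = FALSE),
    `TF-IDF_Top_Kmeans` = entry("tfidf_top", "kmeans"),
    `TF-IDF_Var_Kmeans` = entry("tfidf_var", "kmeans"),
    `TF-IDF_Top_sKmeans` = entry("tfidf_top", "skmeans"),
    `TF-IDF_Var_sKmeans` = entry("tfidf_var", "skmeans"),
    `TF-IDF_Top_HC_E`   = entry("tfidf_top", "hc", "euclidean"),
    `TF-IDF_Top_HC_P`   = entry("tfidf_top", "hc", "pearson"),
    `TF-IDF_Top_HC_C`   = entry("tfidf_top", "hc", "cosine"),
    `TF-IDF_Var_HC_E`   = entry("tfidf_var", "hc", "euclidean", selected = FALSE),
    `TF-IDF_Var_HC_P`   = entry("tfidf_var", "hc", "pearson", selected = FALSE),
    `TF-IDF_Var_HC_C`   = entry("tfidf_var", "hc", "cosine", selected = FALSE),
    `TF-IDF_Bin_HC_E`   = entry("tfidf_bin", "hc", "euclidean"),
    `TF-IDF_Bin_HC_P`   = entry("tfidf_bin", "hc", "pearson"),
    `TF-IDF_Bin_HC_C`   = entry("tfidf_bin", "hc", "cosine"),
    `TF-IDF_Bin_HC_J`   = entry("tfidf_bin", "hc", "jaccard"),
    `TF-IDF_Bin_Greedy_E` = entry("tfidf_bin", "greedy", "euclidean"),
    `TF-IDF_Bin_Greedy_P` = entry("tfidf_bin", "greedy", "pearson"),
    `TF-IDF_Bin_Greedy_C` = entry("tfidf_bin", "greedy", "cosine"),
    `TF-IDF_Bin_Greedy_J` = entry("tfidf_bin", "greedy", "jaccard"),
    `TF-IDF_Bin_Louvain_E` = entry("tfidf_bin", "louvain", "euclidean"),
    `TF-IDF_Bin_Louvain_P` = entry("tfidf_bin", "louvain", "pearson"),
    `TF-IDF_Bin_Louvain_C` = entry("tfidf_bin", "louvain", "cosine"),
    `TF-IDF_Bin_Louvain_J` = entry("tfidf_bin", "louvain", "jaccard")
  )
})

#' List the implemented clustering methods
#'
#' @param selected_only if `TRUE` (default), only the 26 methods retained
#'   after the 2-class accuracy screen; `FALSE` lists all 34 implemented
#'   compositions.
#' @return Character vector of method names accepted by [run_method()].
#' @export
list_methods <- function(selected_only = TRUE) {
  reg <- .method_registry
  if (selected_only) reg <- Filter(function(e) e$selected, reg)
  names(reg)
}

.default_config <- function() {
  list(top_cap = 3000, var_fraction = 0.30, binarize_multiplier = 0.1,
       graph_cutoff = 0.01, silhouette_threshold = 0.25, min_k = 1,
       pca_components = 10, tsne_perplexity = 30,
       gap_k_max = 10, gap_b_refs = 50)
}

# transformation front-end: CountMatrix -> dense features x cells matrix
.apply_front <- function(front, m, cfg, seed) {
  switch(front,
    log = log_transform(m),
    log_pca = pca_front(log_transform(m), cfg$pca_components),
    tsne = tsne_front(log_transform(m), cfg$tsne_perplexity, seed),
    tfidf_top = {
      t <- compute_tfidf(m)
      sel <- select_genes_top(t, max_genes = cfg$top_cap, seed = seed)
      as.matrix(t$scores[sel$selected_gene_ids, , drop = FALSE])
    },
    tfidf_var = {
      t <- compute_tfidf(m)
      sel <- select_genes_var(t, keep_fraction = cfg$var_fraction)
      as.matrix(t$scores[sel$selected_gene_ids, , drop = FALSE])
    },
    tfidf_bin = {
      t <- compute_tfidf(m)
      as.matrix(binarize(t, multiplier = cfg$binarize_multiplier)$signatures)
    },
    stop_value("unknown front: ", front))
}

#' Run a named clustering method end-to-end
#'
#' Composes the transformation front-end and clustering back-end named by
#' one of the registry methods (see [list_methods()]), e.g.
#' `TF-IDF_Bin_Louvain_C` = TF-IDF transform, binarization, pairwise cosine
#' distances, dense weighted graph, Louvain modularity clustering with
#' silhouette-driven recursive re-partitioning; `Log_PCA_Kmeans` =
#' log2(x+1), top-10 PCA, k-means.
#'
#' For non-graph methods `k = "auto"` resolves the number of clusters with
#' the gap statistic computed on the method's own transformed
#' representation; graph methods determine k internally and interpret a
#' numeric `k` as the minimum number of clusters to enforce via recursive
#' re-partitioning.
#'
#' @param name method name from the registry.
#' @param m a `CountMatrix`.
#' @param k number of clusters, or `"auto"`.
#' @param seed RNG seed; identical inputs and seed give identical labels.
#' @param config named list overriding entries of the default configuration
#'   (top_cap, var_fraction, binarize_multiplier, graph_cutoff,
#'   silhouette_threshold, min_k, pca_components, tsne_perplexity,
#'   gap_k_max, gap_b_refs).
#' @return A `ClusterAssignment` whose `params` record the full composition.
#' @export
run_method <- function(name, m, k = "auto", seed = 1, config = list()) {
  reg <- .method_registry
  if (!name %in% names(reg))
    stop_value("unknown method '", name, "'; valid names: ",
               paste(names(reg), collapse = ", "))
  e <- reg[[name]]
  cfg <- utils::modifyList(.default_config(), config)
  rep_m <- .apply_front(e$front, m, cfg, seed)

  graph_algo <- e$algo %in% c("greedy", "louvain")
  if (!graph_algo) {
    kk <- if (identical(k, "auto")) {
      clusterer <- .gap_clusterer(e)
      gap_statistic(rep_m, clusterer, k_max = cfg$gap_k_max,
                    b_refs = cfg$gap_b_refs, seed = seed)$k_star
    } else as.integer(k)
    out <- switch(e$algo,
      kmeans = kmeans_cluster(rep_m, kk, seed),
      skmeans = spherical_kmeans(rep_m, kk, seed),
      gmm = gmm_em(rep_m, kk, seed),
      hc = hierarchical_ward(pairwise_distances(rep_m, e$metric), kk))
  } else {
    min_k <- if (identical(k, "auto")) cfg$min_k else as.integer(k)
    pipe <- .graph_pipeline(e, cfg, seed)
    top <- pipe(m)
    out <- recursive_partition(m, pipe, base = top$assignment, dist = top$dist,
                               min_k = min_k,
                               silhouette_threshold = cfg$silhouette_threshold)
  }
  out$method <- name
  out$params <- c(out$params, list(method = name, k_requested = k, seed = seed,
                                   config = cfg))
  out
}

# clusterer handed to the gap statistic: same back-end as the method, except
# that binary-only representations (Jaccard) fall back to k-means because the
# uniform-box reference draws are continuous
.gap_clusterer <- function(e) {
  if (e$algo == "hc" && e$metric != "jaccard") {
    function(mm, k, s) hierarchical_ward(pairwise_distances(mm, e$metric), k)
  } else switch(e$algo,
    kmeans = kmeans_cluster,
    skmeans = spherical_kmeans,
    gmm = gmm_em,
    kmeans_cluster)
}

# graph-method pipeline closure: re-applied to count submatrices during
# recursive re-partitioning
.graph_pipeline <- function(e, cfg, seed) {
  function(sub) {
    rep_s <- .apply_front(e$front, sub, cfg, seed)
    d <- pairwise_distances(rep_s, e$metric)
    g <- build_cell_graph(d, cutoff = cfg$graph_cutoff)
    list(assignment = cluster_graph(g, algorithm = e$algo, seed = seed),
         dist = d)
  }
}
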