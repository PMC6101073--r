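#' Cluster assignment container
#'
#' Per-cell integer cluster ids (0-based, contiguous, ordered by first
#' occurrence) plus provenance: the method name, its parameters, and the
#' number of clusters.
#'
#' @param labels integer vector (named by cell id when available).
#' @param method method name string.
#' @param params named list of parameters.
#' @return A `ClusterAssignment`.
#' @keywords internal
new_cluster_assignment <- function(labels, method, params = list()) {
  ids <- names(labels)
  labels <- .relabel(as.integer(labels))
  names(labels) <- ids
  structure(list(labels = labels, method = method, params = params,
                 k = length(unique(labels))),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells in %d clusters (%s)\n",
              length(x$labels), x$k, x$method))
  invisible(x)
}

# k-means++ seeding: returns k column indices of X (n x d matrix of points)
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - rep(X[centers[1], ], each = n))^2)
  if (k > 1) for (j in 2:k) {
    if (sum(d2) == 0) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2)
    }
    dj <- rowSums((X - rep(X[centers[j], ], each = n))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

# Lloyd iterations; X n x d, C k x d initial centers. Empty clusters are
# reseeded with the point farthest from its center.
.lloyd <- function(X, C, max_iter = 100) {
  n <- nrow(X); k <- nrow(C)
  xx <- rowSums(X^2)
  assign_old <- rep(-1L, n)
  for (it in seq_len(max_iter)) {
    D <- outer(xx, rowSums(C^2), "+") - 2 * X %*% t(C)
    lab <- max.col(-D, ties.method = "first")
    empt <- which(tabulate(lab, k) == 0)
    if (length(empt)) {
      cur <- D[cbind(seq_len(n), lab)]
      for (j in empt) {
        far <- which.max(cur)
        lab[far] <- j
        cur[far] <- -Inf
      }
    }
    if (identical(lab, assign_old)) break
    assign_old <- lab
    for (j in seq_len(k)) C[j, ] <- colMeans(X[lab == j, , drop = FALSE])
  }
  D <- outer(xx, rowSums(C^2), "+") - 2 * X %*% t(C)
  wss <- sum(pmax(D[cbind(seq_len(n), lab)], 0))
  list(labels = lab, centers = C, tot_withinss = wss)
}

#' K-means clustering of cells
#'
#' Lloyd-style k-means with k-means++ initialization, 10 restarts and a
#' fixed seed, minimizing total intra-cluster variance. Columns of `m` are
#' the points (cells).
#'
#' @param m numeric matrix, features x cells.
#' @param k number of clusters (1 <= k <= number of cells).
#' @param seed RNG seed.
#' @param n_restart number of k-means++ restarts (default 10).
#' @return A `ClusterAssignment`.
#' @export
kmeans_cluster <- function(m, k, seed = 1, n_restart = 10) {
  X <- t(as.matrix(m))
  n <- nrow(X)
  if (k < 1 || k > n) stop_value("k must be between 1 and the number of cells (", n, ")")
  if (k == 1) {
    lab <- stats::setNames(rep(0L, n), rownames(X))
    return(new_cluster_assignment(lab, "kmeans", list(k = k, seed = seed)))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restart)) {
      C <- X[.kmeanspp_init(X, k), , drop = FALSE]
      fit <- .lloyd(X, C)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
  })
  lab <- stats::setNames(best$labels, rownames(X))
  new_cluster_assignment(lab, "kmeans",
                         list(k = k, seed = seed, tot_withinss = best$tot_withinss))
}

#' Spherical k-means clustering of cells
#'
#' K-means under the cosine dissimilarity: cells are L2-normalized and Lloyd
#' iterations alternate between assigning each cell to the centroid with
#' largest dot product and re-normalizing centroid means to the unit sphere.
#' Assignments are invariant to positive rescaling of any cell.
#'
#' @inheritParams kmeans_cluster
#' @return A `ClusterAssignment`.
#' @export
spherical_kmeans <- function(m, k, seed = 1, n_restart = 10) {
  X <- t(as.matrix(m))
  n <- nrow(X)
  if (k < 1 || k > n) stop_value("k must be between 1 and the number of cells (", n, ")")
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop_value("zero-norm cell: ", rownames(X)[which(nrm == 0)[1]])
  X <- X / nrm
  if (k == 1) {
    lab <- stats::setNames(rep(0L, n), rownames(X))
    return(new_cluster_assignment(lab, "skmeans", list(k = k, seed = seed)))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restart)) {
      C <- X[.kmeanspp_init(X, k), , drop = FALSE]
      lab_old <- rep(-1L, n)
      for (it in seq_len(100)) {
        S <- X %*% t(C) # cosine similarity since rows unit-norm
        lab <- max.col(S, ties.method = "first")
        for (j in which(tabulate(lab, k) == 0)) {
          lab[which.min(S[cbind(seq_len(n), lab)])] <- j
        }
        if (identical(lab, lab_old)) break
        lab_old <- lab
        for (j in seq_len(k)) {
          cm <- colMeans(X[lab == j, , drop = FALSE])
          cn <- sqrt(sum(cm^2))
          C[j, ] <- if (cn > 0) cm / cn else X[sample.int(n, 1), ]
        }
      }
      obj <- sum(1 - (X %*% t(C))[cbind(seq_len(n), lab)])
      if (is.null(best) || obj < best$obj) best <- list(obj = obj, labels = lab)
    }
  })
  lab <- stats::setNames(best$labels, rownames(X))
  new_cluster_assignment(lab, "skmeans", list(k = k, seed = seed, objective = best$obj))
}

# multivariate normal log-density with covariance regularization;
# returns NULL if the covariance cannot be factorized
.mvn_logdens <- function(X, mu, sigma) {
  d <- ncol(X)
  ch <- tryCatch(chol(sigma + diag(1e-8, d)), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' EM Gaussian-mixture clustering of cells
#'
#' Fits a k-component Gaussian mixture by expectation-maximization with full
#' covariance matrices (5 seeded restarts, k-means++ based initialization)
#' and hard-assigns each cell to its maximum-posterior component. When a
#' full covariance is singular (or the dimensionality exceeds the number of
#' cells) the fit falls back to diagonal covariances with a warning.
#'
#' @inheritParams kmeans_cluster
#' @param n_restart number of restarts (default 5).
#' @return A `ClusterAssignment`; `params$loglik` holds the per-iteration
#'   log-likelihood trace of the winning restart (non-decreasing).
#' @export
gmm_em <- function(m, k, seed = 1, n_restart = 5) {
  X <- t(as.matrix(m))
  n <- nrow(X); d <- ncol(X)
  if (k < 1 || k > n) stop_value("k must be between 1 and the number of cells (", n, ")")
  if (k == 1 || n == k) {
    lab <- if (k == 1) rep(0L, n) else seq_len(n) - 1L
    return(new_cluster_assignment(stats::setNames(lab, rownames(X)), "gmm",
                                  list(k = k, seed = seed)))
  }
  diagonal <- d >= n
  if (diagonal) warning("dimension >= number of cells; using diagonal covariances")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restart)) {
      init <- .lloyd(X, X[.kmeanspp_init(X, k), , drop = FALSE], max_iter = 10)$labels
      w <- tabulate(init, k) / n
      mu <- lapply(seq_len(k), function(j) colMeans(X[init == j, , drop = FALSE]))
      gv <- pmax(apply(X, 2L, stats::var), 1e-8)
      sig <- lapply(seq_len(k), function(j) {
        Xi <- X[init == j, , drop = FALSE]
        if (diagonal || nrow(Xi) <= d) diag(gv, d)
        else stats::cov(Xi) + diag(1e-6 * mean(gv), d)
      })
      ll_trace <- numeric(0)
      ll_old <- -Inf
      lp <- NULL
      use_diag <- diagonal
      for (it in seq_len(200)) {
        lp <- matrix(0, n, k)
        for (j in seq_len(k)) {
          ld <- if (use_diag) {
            dv <- pmax(diag(sig[[j]]), 1e-8)
            -0.5 * d * log(2 * pi) - 0.5 * sum(log(dv)) -
              0.5 * colSums(((t(X) - mu[[j]])^2) / dv)
          } else .mvn_logdens(X, mu[[j]], sig[[j]])
          if (is.null(ld)) {
            warning("singular covariance; falling back to diagonal covariances")
            use_diag <- TRUE
            dv <- pmax(diag(sig[[j]]), 1e-8)
            ld <- -0.5 * d * log(2 * pi) - 0.5 * sum(log(dv)) -
              0.5 * colSums(((t(X) - mu[[j]])^2) / dv)
          }
          lp[, j] <- log(w[j]) + ld
        }
        lse <- .row_logsumexp(lp)
        ll <- sum(lse)
        ll_trace <- c(ll_trace, ll)
        g <- exp(lp - lse)
        nk <- pmax(colSums(g), 1e-10)
        w <- nk / n
        for (j in seq_len(k)) {
          mu[[j]] <- colSums(g[, j] * X) / nk[j]
          Xc <- t(t(X) - mu[[j]])
          if (use_diag) {
            sig[[j]] <- diag(pmax(colSums(g[, j] * Xc^2) / nk[j], 1e-8), d)
          } else {
            sig[[j]] <- crossprod(Xc * sqrt(g[, j])) / nk[j] + diag(1e-8, d)
          }
        }
        if (is.finite(ll_old) && abs(ll - ll_old) < 1e-8 * (1 + abs(ll))) break
        ll_old <- ll
      }
      if (is.null(best) || ll_old > best$ll)
        best <- list(ll = ll_old, labels = max.col(lp, ties.method = "first"),
                     trace = ll_trace)
    }
  })
  lab <- stats::setNames(best$labels, rownames(X))
  new_cluster_assignment(lab, "gmm", list(k = k, seed = seed, loglik = best$trace))
}

#' Hierarchical clustering with Ward linkage
#'
#' Agglomerative clustering on an arbitrary precomputed dissimilarity matrix
#' using the Ward criterion (Lance-Williams update applied to the supplied
#' dissimilarities; `stats::hclust` method `"ward.D2"`), with the tree cut
#' at `k` clusters. The same linkage is paired with Euclidean, Pearson,
#' cosine, and Jaccard distances throughout the package.
#'
#' @param d a `DistanceMatrix` (or symmetric matrix).
#' @param k number of clusters.
#' @return A `ClusterAssignment`.
#' @export
hierarchical_ward <- function(d, k) {
  dm <- if (inherits(d, "DistanceMatrix")) d$d else as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop_value("distance matrix is not symmetric")
  n <- nrow(dm)
  if (k < 1 || k > n) stop_value("k must be between 1 and ", n)
  hc <- stats::hclust(stats::as.dist(dm), method = "ward.D2")
  lab <- stats::cutree(hc, k = k)
  new_cluster_assignment(stats::setNames(as.integer(lab), rownames(dm)),
                         "hierarchical_ward",
                         list(k = k, metric = if (inherits(d, "DistanceMatrix")) d$metric else NA))
}

#' Build a dense weighted cell graph from distances
#'
#' Min-max scales the pairwise distances to \[0, 1\] and connects every pair
#' of cells whose scaled distance is at least `cutoff`, weighting each edge
#' by the similarity 1 - scaled distance. With the default low cutoff of
#' 0.01 this yields a dense weighted graph. The pair attaining the maximum
#' distance would receive weight 0 and is dropped so all weights lie in
#' (0, 1]; isolated vertices are permitted.
#'
#' @param d a `DistanceMatrix`.
#' @param cutoff scaled-distance threshold in \[0, 1) (default 0.01).
#' @param rule `"distance_ge"` (default; edges where scaled distance >=
#'   cutoff, dense) or `"distance_le"` (edges where scaled distance <=
#'   cutoff, the literal sparse reading).
#' @return A `CellGraph`: list with igraph `graph`, `metric`, `cell_ids`.
#' @export
build_cell_graph <- function(d, cutoff = 0.01, rule = c("distance_ge", "distance_le")) {
  rule <- match.arg(rule)
  stopifnot(cutoff >= 0, cutoff < 1)
  dm <- d$d
  n <- nrow(dm)
  if (n < 2) stop_value("need at least 2 cells to build a graph")
  off <- dm[upper.tri(dm)]
  rng <- range(off)
  if (rng[1] == rng[2]) stop_value("all pairwise distances equal; scaling degenerate")
  sc <- (dm - rng[1]) / (rng[2] - rng[1])
  ut <- which(upper.tri(sc), arr.ind = TRUE)
  sv <- sc[ut]
  sel <- if (rule == "distance_ge") sv >= cutoff & sv < 1 else sv <= cutoff & sv < 1
  # the pair at scaled distance exactly 1 would get weight 0: dropped
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  ids <- rownames(dm)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (any(sel)) {
    ed <- ut[sel, , drop = FALSE]
    g <- igraph::add_edges(g, rbind(ed[, 1], ed[, 2]),
                           weight = 1 - sv[sel])
  }
  structure(list(graph = g, metric = d$metric, cell_ids = ids),
            class = "CellGraph")
}

#' @export
print.CellGraph <- function(x, ...) {
  cat(sprintf("CellGraph (%s): %d vertices, %d edges\n", x$metric,
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Modularity-based community detection on a cell graph
#'
#' Weighted modularity optimization: `"greedy"` is the agglomerative
#' Clauset-Newman-Moore algorithm (igraph `cluster_fast_greedy`),
#' `"louvain"` the multilevel local-moving algorithm (igraph
#' `cluster_louvain`). The number of clusters is determined internally.
#'
#' @param g a `CellGraph`.
#' @param algorithm `"louvain"` or `"greedy"`.
#' @param seed RNG seed (Louvain vertex-order is randomized).
#' @return A `ClusterAssignment`; `params$modularity` holds the achieved
#'   modularity.
#' @export
cluster_graph <- function(g, algorithm = c("louvain", "greedy"), seed = 1) {
  algorithm <- match.arg(algorithm)
  gr <- g$graph
  if (igraph::vcount(gr) == 0) stop_value("empty graph")
  memb <- with_seed(seed, {
    cm <- if (algorithm == "louvain") igraph::cluster_louvain(gr)
          else igraph::cluster_fast_greedy(gr)
    igraph::membership(cm)
  })
  mod <- igraph::modularity(gr, memb,
                            weights = igraph::E(gr)$weight)
  lab <- stats::setNames(as.integer(memb), g$cell_ids)
  new_cluster_assignment(lab, paste0("graph_", algorithm),
                         list(algorithm = algorithm, seed = seed,
                              modularity = mod, metric = g$metric))
}

#' Mean silhouette width per cluster
#'
#' Standard silhouette widths computed from a full distance matrix;
#' singleton clusters get silhouette 0 by convention. Returns the mean
#' width of each cluster.
#'
#' @param d a `DistanceMatrix`.
#' @param labels integer vector of cluster ids (0-based).
#' @return Named numeric vector, one mean silhouette per cluster id.
#' @export
cluster_silhouette <- function(d, labels) {
  dm <- if (inherits(d, "DistanceMatrix")) d$d else as.matrix(d)
  labels <- as.integer(labels)
  ids <- sort(unique(labels))
  if (length(ids) < 2)
    return(stats::setNames(rep(NA_real_, length(ids)), ids))
  n <- length(labels)
  s <- numeric(n)
  md <- sapply(ids, function(j) rowMeans(dm[, labels == j, drop = FALSE]))
  sizes <- tabulate(labels + 1L, max(labels) + 1L)[ids + 1L]
  for (i in seq_len(n)) {
    own <- which(ids == labels[i])
    ni <- sizes[own]
    if (ni == 1) { s[i] <- 0; next }
    a <- md[i, own] * ni / (ni - 1) # exclude self distance (0)
    b <- min(md[i, -own])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  stats::setNames(vapply(ids, function(j) mean(s[labels == j]), 0), ids)
}

#' Silhouette-driven recursive re-partitioning
#'
#' Iteratively refines a base clustering to enforce a minimum number of
#' clusters: while k < min_k and some cluster has mean silhouette below
#' `silhouette_threshold`, the worst such cluster's cells are extracted into
#' a new count submatrix, the full transformation pipeline (e.g. TF-IDF,
#' binarization, graph clustering) is re-applied to that submatrix, and the
#' cluster is replaced by the resulting sub-clusters. The process repeats
#' until the minimum number of clusters is achieved or no cluster is below
#' the threshold (also stopping when no eligible cluster remains;
#' sub-clusters of fewer than 3 cells are never re-partitioned). A
#' single-cluster base (silhouette undefined) counts as below threshold
#' exactly when min_k > 1.
#'
#' @param m the `CountMatrix` the base assignment was computed from.
#' @param pipeline function taking a `CountMatrix` and returning a list with
#'   elements `assignment` (a `ClusterAssignment`) and `dist` (a
#'   `DistanceMatrix` in the pipeline's own representation).
#' @param base optional starting `ClusterAssignment`; computed by running
#'   `pipeline` on `m` when omitted.
#' @param dist optional full-data `DistanceMatrix` for silhouettes; computed
#'   from `pipeline(m)` when omitted.
#' @param min_k minimum number of clusters to enforce.
#' @param silhouette_threshold clusters with mean silhouette strictly below
#'   this are re-partitioned (default 0.25; -1 disables).
#' @return A refined `ClusterAssignment` with k >= the base k.
#' @export
recursive_partition <- function(m, pipeline, base = NULL, dist = NULL,
                                min_k = 1, silhouette_threshold = 0.25) {
  stopifnot(min_k >= 1)
  if (is.null(base) || is.null(dist)) {
    top <- pipeline(m)
    if (is.null(base)) base <- top$assignment
    if (is.null(dist)) dist <- top$dist
  }
  labels <- base$labels
  cells <- cell_ids(m)
  if (is.null(names(labels))) names(labels) <- cells
  failed <- integer(0)
  n <- length(labels)
  for (iter in seq_len(n)) {
    k <- length(unique(labels))
    ids <- sort(unique(labels))
    sizes <- vapply(ids, function(j) sum(labels == j), 0L)
    # silhouette is undefined for a single cluster: treat it as failing when
    # a minimum of more than one cluster must be enforced, passing otherwise
    sil <- if (k >= 2) cluster_silhouette(dist, labels)
           else stats::setNames(if (min_k > 1) -Inf else Inf, ids)
    # stop rule: the minimum number of clusters was achieved, or no cluster
    # has a silhouette below the given threshold; without the min_k cap,
    # re-partitioning would shred similar types into ever-purer slivers
    if (k >= min_k || !any(sil < silhouette_threshold)) break
    eligible <- ids[sizes >= 3 & !(ids %in% failed)]
    below <- intersect(eligible, ids[sil[as.character(ids)] < silhouette_threshold])
    target <- if (length(below)) below[which.min(sil[as.character(below)])]
              else NA_integer_
    if (is.na(target)) break
    sub_cells <- names(labels)[labels == target]
    res <- tryCatch(pipeline(m[, sub_cells]), error = function(e) NULL)
    if (is.null(res) || res$assignment$k < 2) {
      failed <- c(failed, target)
      next
    }
    labels[sub_cells] <- max(labels) + 1L + res$assignment$labels
    labels <- stats::setNames(.relabel(labels), names(labels))
    failed <- integer(0) # ids changed; re-evaluate everything
  }
  new_cluster_assignment(labels, paste0(base$method, "+recursive"),
                         c(base$params, list(min_k = min_k,
                                             silhouette_threshold = silhouette_threshold)))
}
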