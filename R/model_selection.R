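#' Within-cluster dispersion W_k
#'
#' The normalized sum of squared pairwise Euclidean distances inside each
#' cluster: W_k = sum_r D_r / (2 n_r) with D_r the sum of squared distances
#' over all ordered pairs of cluster r. This equals the total within-cluster
#' sum of squares about the centroids, which is how it is computed.
#'
#' @param m numeric matrix, features x cells.
#' @param labels a `ClusterAssignment` or integer label vector.
#' @return W_k as a single number.
#' @export
within_dispersion <- function(m, labels) {
  X <- t(as.matrix(m))
  lab <- if (inherits(labels, "ClusterAssignment")) labels$labels else as.integer(labels)
  if (length(lab) != nrow(X)) stop_value("labels length != number of cells")
  W <- 0
  for (j in unique(lab)) {
    Xi <- X[lab == j, , drop = FALSE]
    if (nrow(Xi) == 0) stop_value("empty cluster ", j)
    W <- W + sum(t(t(Xi) - colMeans(Xi))^2)
  }
  W
}

#' Gap statistic for choosing the number of clusters
#'
#' For each k in 1..k_max, clusters the data and `b_refs` Monte-Carlo
#' reference datasets (drawn uniformly over the per-feature bounding box of
#' the data) with the same clusterer and computes
#' Gap(k) = mean_b log W_k(ref_b) - log W_k(data). The selected number of
#' clusters is the plain argmax of the gap curve. The per-k Monte-Carlo
#' standard error is sd_b(log W_k(ref)) * sqrt(1 + 1/b_refs); the result is
#' flagged when the maximum gap is below twice its standard error (no
#' pronounced cluster structure).
#'
#' @param m numeric matrix, features x cells (already carrying whatever
#'   transformation the downstream clustering method uses — the gap analysis
#'   is performed per transformation).
#' @param clusterer function(matrix, k, seed) returning a
#'   `ClusterAssignment` or an integer label vector; defaults to
#'   [kmeans_cluster()].
#' @param k_max largest candidate k (default 10).
#' @param b_refs number of reference draws (default 50).
#' @param seed RNG seed governing both the reference draws and the seeds
#'   handed to the clusterer.
#' @return A `GapResult`: list with `k_grid`, `gap`, `se`, `log_w`,
#'   `log_w_ref`, `k_star`, `b_refs`, `flagged`.
#' @export
gap_statistic <- function(m, clusterer = kmeans_cluster, k_max = 10,
                          b_refs = 50, seed = 1) {
  stopifnot(k_max >= 2, b_refs >= 2)
  X <- as.matrix(m)
  lo <- apply(X, 1L, min); hi <- apply(X, 1L, max)
  if (all(hi == lo)) stop_value("degenerate matrix: all features constant")
  cl_lab <- function(mm, k, s) {
    a <- clusterer(mm, k, s)
    if (inherits(a, "ClusterAssignment")) a$labels else a
  }
  refs <- with_seed(seed, {
    lapply(seq_len(b_refs), function(b)
      matrix(stats::runif(length(X), min = lo, max = hi), nrow(X), ncol(X)))
  })
  k_grid <- seq_len(k_max)
  log_w <- gap <- se <- rep(NA_real_, k_max)
  log_w_ref <- matrix(NA_real_, b_refs, k_max)
  keep <- rep(TRUE, k_max)
  for (k in k_grid) {
    wk <- within_dispersion(X, cl_lab(X, k, seed + k))
    if (wk <= 0) {
      warning("W_k = 0 for the data at k = ", k, "; excluded")
      keep[k] <- FALSE
      next
    }
    log_w[k] <- log(wk)
    lwr <- vapply(seq_len(b_refs), function(b)
      log(within_dispersion(refs[[b]], cl_lab(refs[[b]], k, seed + 1000 * b + k))),
      0)
    log_w_ref[, k] <- lwr
    gap[k] <- mean(lwr) - log_w[k]
    se[k] <- stats::sd(lwr) * sqrt(1 + 1 / b_refs)
  }
  if (!any(keep)) stop_value("no usable k: all W_k degenerate")
  k_star <- k_grid[keep][which.max(gap[keep])]
  structure(list(k_grid = k_grid[keep], gap = gap[keep], se = se[keep],
                 log_w = log_w[keep], log_w_ref = log_w_ref[, keep, drop = FALSE],
                 k_star = k_star, b_refs = b_refs,
                 flagged = max(gap[keep]) < 2 * se[keep][which.max(gap[keep])]),
            class = "GapResult")
}

#' @export
print.GapResult <- function(x, ...) {
  cat(sprintf("GapResult: k_star = %d (b_refs = %d%s)\n", x$k_star, x$b_refs,
              if (x$flagged) ", flagged: no pronounced maximum" else ""))
  print(data.frame(k = x$k_grid, gap = round(x$gap, 4), se = round(x$se, 4)))
  invisible(x)
}

#' Write a GapResult as TSV
#'
#' @param x a `GapResult`.
#' @param path output path; columns k, gap, se.
#' @export
write_gap_result <- function(x, path) {
  utils::write.table(data.frame(k = x$k_grid, gap = x$gap, se = x$se),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
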