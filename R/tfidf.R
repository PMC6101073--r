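#' Term frequency per cell
#'
#' TF of gene i in cell j is the count divided by the largest count of any
#' gene in the same cell, so the most frequent gene of every cell scores
#' exactly 1 and all others get fractional values. Cells with no nonzero
#' count are rejected.
#'
#' @param m a `CountMatrix`.
#' @return Sparse genes x cells matrix of TF values in \[0, 1\].
#' @export
compute_tf <- function(m) {
  v <- counts(m)
  mx <- apply(v, 2L, max)
  if (any(mx == 0))
    stop_value("cell with all-zero counts: ", cell_ids(m)[which(mx == 0)[1]])
  v %*% Matrix::Diagonal(x = 1 / mx, names = FALSE)
}

#' Inverse document frequency per gene
#'
#' IDF of gene i is log2(N / n_i) where N is the number of cells and n_i the
#' number of cells detecting the gene (count > 0). Genes detected nowhere
#' get IDF 0 so the transform stays total (such genes should normally be
#' removed by QC).
#'
#' @param m a `CountMatrix`.
#' @return Named numeric vector of per-gene IDF values.
#' @export
compute_idf <- function(m) {
  N <- ncol(counts(m))
  stopifnot(N >= 1)
  n_i <- Matrix::rowSums(counts(m) > 0)
  idf <- ifelse(n_i > 0, log2(N / n_i), 0)
  stats::setNames(idf, gene_ids(m))
}

#' TF-IDF scores
#'
#' Elementwise product of the per-cell term frequencies and the per-gene
#' inverse document frequency: score(i, j) = TF_ij * IDF_i. A zero count
#' always yields a zero score, and a gene detected in every cell has IDF 0
#' and therefore a zero score everywhere.
#'
#' @param m a `CountMatrix`.
#' @return A `TfidfMatrix`: list with `scores` (sparse genes x cells),
#'   `idf`, `n_detect` (cells detecting each gene), `gene_ids`, `cell_ids`.
#' @examples
#' m <- count_matrix(matrix(c(2, 8, 4, 0, 1, 1), 3), paste0("g", 1:3),
#'                   c("c1", "c2"))
#' compute_tfidf(m)$scores
#' @export
compute_tfidf <- function(m) {
  tf <- compute_tf(m)
  idf <- compute_idf(m)
  scores <- Matrix::Diagonal(x = idf, names = FALSE) %*% tf
  scores <- methods::as(methods::as(scores, "generalMatrix"), "CsparseMatrix")
  scores <- Matrix::drop0(scores)
  dimnames(scores) <- list(gene_ids(m), cell_ids(m))
  structure(list(scores = scores, idf = idf,
                 n_detect = Matrix::rowSums(counts(m) > 0),
                 gene_ids = gene_ids(m), cell_ids = cell_ids(m)),
            class = "TfidfMatrix")
}

#' @export
print.TfidfMatrix <- function(x, ...) {
  cat(sprintf("TfidfMatrix: %d genes x %d cells\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' "Top" gene selection: high-average TF-IDF component of a 2-mixture GMM
#'
#' Fits a univariate 2-component Gaussian mixture to the per-gene mean TF-IDF
#' scores (EM, 5 seeded restarts) and keeps the genes whose most probable
#' component is the one with the larger fitted mean. If more than `max_genes`
#' genes qualify, only the top `max_genes` ranked by the number of cells in
#' which they are detected are retained.
#'
#' @param t a `TfidfMatrix`.
#' @param max_genes cap on the selection (default 3000; `Inf` disables).
#' @param seed RNG seed for the restarts.
#' @return A `GeneSelection` with `selected_gene_ids`, `method = "top"` and a
#'   per-gene `diagnostics` data frame (mean, component, detection count).
#' @export
select_genes_top <- function(t, max_genes = 3000, seed = 1) {
  mu <- Matrix::rowMeans(t$scores)
  if (length(unique(mu)) < 2) stop_value("degenerate fit: all gene means equal")
  fit <- .gmm1d_2comp(mu, seed = seed)
  hi <- which.max(fit$means)
  comp <- fit$assignment
  sel <- which(comp == hi)
  if (is.finite(max_genes) && length(sel) > max_genes) {
    ord <- order(-t$n_detect[sel], sel)
    sel <- sel[ord[seq_len(max_genes)]]
    sel <- sort(sel)
  }
  structure(list(selected_gene_ids = t$gene_ids[sel], method = "top",
                 diagnostics = data.frame(gene_id = t$gene_ids, mean = mu,
                                          component = comp,
                                          n_detect = t$n_detect,
                                          selected = seq_along(mu) %in% sel),
                 fit = fit[c("means", "sds", "weights")]),
            class = "GeneSelection")
}

# univariate 2-component Gaussian mixture via EM with restarts
.gmm1d_2comp <- function(x, seed = 1, n_restart = 5, max_iter = 300, tol = 1e-9) {
  n <- length(x)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restart)) {
      q <- stats::quantile(x, probs = c(0.25, 0.75), names = FALSE)
      mu <- q + stats::rnorm(2, 0, stats::sd(x) * 0.1 + 1e-12)
      sg <- rep(stats::sd(x) * 0.5 + 1e-12, 2)
      w <- c(0.5, 0.5)
      ll_old <- -Inf
      for (it in seq_len(max_iter)) {
        lp <- cbind(log(w[1]) + stats::dnorm(x, mu[1], sg[1], log = TRUE),
                    log(w[2]) + stats::dnorm(x, mu[2], sg[2], log = TRUE))
        lse <- .row_logsumexp(lp)
        ll <- sum(lse)
        g <- exp(lp - lse)
        nk <- colSums(g)
        w <- nk / n
        mu <- colSums(g * x) / nk
        sg <- sqrt(pmax(colSums(g * (x - rep(mu, each = n))^2) / nk, 1e-12))
        if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
        ll_old <- ll
      }
      if (is.null(best) || ll > best$ll)
        best <- list(ll = ll, means = mu, sds = sg, weights = w,
                     assignment = max.col(lp, ties.method = "first"))
    }
  })
  best
}

#' "Var" gene selection: high TF-IDF variability relative to the mean-CV trend
#'
#' Computes each gene's mean TF-IDF and coefficient of variation (sample
#' sd / mean, over all cells), fits an ordinary least-squares line of log(CV)
#' on log(mean), and ranks genes by their residual (observed minus predicted
#' log CV). The top `keep_fraction` of eligible genes by residual is
#' returned; genes with zero mean or zero CV are excluded before fitting.
#'
#' @param t a `TfidfMatrix`.
#' @param keep_fraction fraction of eligible genes to keep (default 0.30).
#' @return A `GeneSelection` with `method = "var"` and per-gene diagnostics
#'   (mean, CV, residual).
#' @export
select_genes_var <- function(t, keep_fraction = 0.30) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  s <- t$scores
  mu <- Matrix::rowMeans(s)
  n <- ncol(s)
  ex2 <- Matrix::rowSums(s^2) / n
  sdv <- sqrt(pmax(ex2 - mu^2, 0) * n / (n - 1))
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  eligible <- which(mu > 0 & sdv > 0)
  dropped <- length(mu) - length(eligible)
  if (dropped > 0)
    message(dropped, " gene(s) with zero mean or zero variance excluded from CV fit")
  if (length(eligible) < 10)
    stop_value("need at least 10 genes with nonzero mean TF-IDF")
  lx <- log(mu[eligible]); ly <- log(cv[eligible])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  resid <- rep(NA_real_, length(mu))
  resid[eligible] <- fit$residuals
  n_keep <- max(1L, floor(length(eligible) * keep_fraction + 1e-9))
  ord <- eligible[order(-resid[eligible], eligible)]
  sel <- sort(ord[seq_len(n_keep)])
  structure(list(selected_gene_ids = t$gene_ids[sel], method = "var",
                 diagnostics = data.frame(gene_id = t$gene_ids, mean = mu,
                                          cv = cv, residual = resid,
                                          selected = seq_along(mu) %in% sel),
                 coef = fit$coefficients),
            class = "GeneSelection")
}

#' @export
print.GeneSelection <- function(x, ...) {
  cat(sprintf("GeneSelection (%s): %d genes selected\n",
              x$method, length(x$selected_gene_ids)))
  invisible(x)
}

#' Binarize TF-IDF scores into per-cell expression signatures
#'
#' For each cell the cutoff is `multiplier` times the mean of that cell's
#' nonzero TF-IDF scores; the signature of every gene scoring strictly above
#' the cutoff is 1, all others 0. With `multiplier = 0` every nonzero score
#' becomes 1, i.e. the detection mask of the counts (up to genes whose IDF is
#' zero because they are detected in every cell). With `global = TRUE` a
#' single cutoff (multiplier times the mean over all nonzero scores in the
#' matrix) is used for every cell instead.
#'
#' @param t a `TfidfMatrix`.
#' @param multiplier cutoff multiplier (default 0.1, the value at which near
#'   maximum clustering accuracy is attained).
#' @param global use one matrix-wide cutoff instead of per-cell cutoffs.
#' @return A `BinarySignatureMatrix`: list with `signatures` (sparse 0/1
#'   genes x cells) and `cutoff_used` (per-cell numeric vector).
#' @export
binarize <- function(t, multiplier = 0.1, global = FALSE) {
  stopifnot(multiplier >= 0)
  s <- t$scores
  nz_per_cell <- Matrix::colSums(s > 0)
  if (any(nz_per_cell == 0))
    stop_value("cell with no nonzero TF-IDF score: ",
               t$cell_ids[which(nz_per_cell == 0)[1]])
  if (global) {
    cutoff <- rep(multiplier * sum(s@x) / length(s@x), ncol(s))
  } else {
    cutoff <- multiplier * Matrix::colSums(s) / nz_per_cell
  }
  sig <- s %*% Matrix::Diagonal(x = rep(1, ncol(s)), names = FALSE) # copy
  sig <- methods::as(methods::as(sig, "generalMatrix"), "CsparseMatrix")
  cut_per_entry <- rep(cutoff, diff(sig@p))
  sig@x <- as.numeric(sig@x > cut_per_entry)
  sig <- Matrix::drop0(sig)
  dimnames(sig) <- list(t$gene_ids, t$cell_ids)
  structure(list(signatures = sig,
                 cutoff_used = stats::setNames(cutoff, t$cell_ids),
                 gene_ids = t$gene_ids, cell_ids = t$cell_ids),
            class = "BinarySignatureMatrix")
}

#' @export
print.BinarySignatureMatrix <- function(x, ...) {
  cat(sprintf("BinarySignatureMatrix: %d genes x %d cells (%.2f%% ones)\n",
              nrow(x$signatures), ncol(x$signatures),
              100 * length(x$signatures@x) / prod(dim(x$signatures))))
  invisible(x)
}
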