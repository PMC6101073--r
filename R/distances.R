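#' Distance kernels between cells
#'
#' Scalar kernels used throughout the package. `cosine_dissimilarity` is
#' 1 - cos(theta) between two feature vectors (range \[0, 2\]);
#' `jaccard_distance` is 1 minus the ratio of shared to united 0/1
#' signatures (range \[0, 1\]); `pearson_distance` is 1 - r (range \[0, 2\]).
#' Degenerate inputs (zero norm, zero variance, both signatures empty) raise
#' an error rather than returning a sentinel, so upstream QC failures
#' surface immediately.
#'
#' @param a,b numeric vectors of equal length (0/1 for Jaccard).
#' @return A single dissimilarity value.
#' @examples
#' cosine_dissimilarity(c(1, 0), c(1, 1)) # 1 - 1/sqrt(2)
#' jaccard_distance(c(1, 1, 0), c(1, 0, 1)) # 2/3
#' @export
cosine_dissimilarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_value("zero-norm vector in cosine dissimilarity")
  max(0, 1 - sum(a * b) / (na * nb))
}

#' @rdname cosine_dissimilarity
#' @export
jaccard_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop_value("jaccard distance requires binary vectors")
  un <- sum(a | b)
  if (un == 0) stop_value("both vectors all-zero in jaccard distance")
  1 - sum(a & b) / un
}

#' @rdname cosine_dissimilarity
#' @export
pearson_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_value("zero-variance vector in pearson distance")
  max(0, 1 - stats::cor(a, b))
}

#' Pairwise cell-cell distance matrix
#'
#' Applies one of the four kernels to all pairs of columns (cells) of a
#' features x cells matrix, vectorized. Euclidean is the L2 norm of column
#' differences; Jaccard requires a 0/1 matrix.
#'
#' @param m numeric matrix (features x cells), dense or sparse.
#' @param metric one of `"euclidean"`, `"pearson"`, `"cosine"`, `"jaccard"`.
#' @return A `DistanceMatrix`: list with symmetric matrix `d` (zero diagonal)
#'   and `metric`.
#' @export
pairwise_distances <- function(m, metric = c("euclidean", "pearson", "cosine",
                                             "jaccard")) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  n <- ncol(m)
  if (n < 2) stop_value("need at least 2 cells for pairwise distances")
  ids <- colnames(m)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- switch(metric,
    euclidean = {
      as.matrix(stats::dist(t(m)))
    },
    pearson = {
      sds <- apply(m, 2L, stats::sd)
      if (any(sds == 0))
        stop_value("zero-variance cell in pearson distance: ", ids[which(sds == 0)[1]])
      1 - stats::cor(m)
    },
    cosine = {
      nrm <- sqrt(colSums(m^2))
      if (any(nrm == 0))
        stop_value("zero-norm cell in cosine distance: ", ids[which(nrm == 0)[1]])
      1 - crossprod(sweep(m, 2L, nrm, "/"))
    },
    jaccard = {
      if (!all(m %in% c(0, 1)))
        stop_value("jaccard metric requires a binary matrix")
      sz <- colSums(m)
      if (any(sz == 0))
        stop_value("all-zero cell in jaccard distance: ", ids[which(sz == 0)[1]])
      inter <- crossprod(m)
      un <- outer(sz, sz, "+") - inter
      1 - inter / un
    })
  d <- as.matrix(d)
  d[d < 0] <- 0
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(list(d = d, metric = metric), class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat(sprintf("DistanceMatrix (%s): %d x %d\n", x$metric, nrow(x$d), ncol(x$d)))
  invisible(x)
}
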