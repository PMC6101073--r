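#' Cell quality filtering
#'
#' Keeps cells with at least `min_genes` detected genes (count > 0) and a
#' total count of at least `min_total_umi`. The gene set is unchanged.
#'
#' @param m a `CountMatrix`.
#' @param min_genes minimum number of detected genes per cell (default 200,
#'   the conventional Seurat-style floor).
#' @param min_total_umi minimum column sum per cell.
#' @return Filtered `CountMatrix`.
#' @export
filter_cells <- function(m, min_genes = 200, min_total_umi = 0) {
  stopifnot(min_genes >= 0, min_total_umi >= 0)
  v <- counts(m)
  keep <- Matrix::colSums(v > 0) >= min_genes & Matrix::colSums(v) >= min_total_umi
  if (!any(keep)) stop_empty("cell filtering removed all cells")
  m[, keep]
}

#' Robust removal of outlier cells
#'
#' Within each group of cells (one group per ground-truth label when `labels`
#' is given, otherwise all cells together), computes the Euclidean distance of
#' each cell's log2(x+1) profile to the group centroid and drops cells whose
#' distance strictly exceeds `median + k_mad * MAD` of the group's distances.
#' The MAD uses the usual normal-consistency constant 1.4826
#' (see [stats::mad()]). Groups of fewer than 3 cells pass through unfiltered
#' with a warning; `k_mad = Inf` is the identity.
#'
#' @param m a `CountMatrix`.
#' @param labels optional named vector mapping every cell id to a group label.
#' @param k_mad MAD multiplier (default 3).
#' @return Filtered `CountMatrix`.
#' @export
remove_cell_outliers_mad <- function(m, labels = NULL, k_mad = 3) {
  cells <- cell_ids(m)
  if (is.null(labels)) {
    grp <- rep("all", length(cells))
  } else {
    if (!all(cells %in% names(labels)))
      stop_value("cells without a label: ",
                 paste(utils::head(setdiff(cells, names(labels)), 3), collapse = ", "))
    grp <- as.character(labels[cells])
  }
  if (!is.finite(k_mad)) return(m)
  L <- as.matrix(log2(counts(m) + 1))
  keep <- rep(TRUE, length(cells))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 3) {
      warning("group '", g, "' has fewer than 3 cells; passed through unfiltered")
      next
    }
    cen <- rowMeans(L[, idx, drop = FALSE])
    d <- sqrt(colSums((L[, idx, drop = FALSE] - cen)^2))
    thr <- stats::median(d) + k_mad * stats::mad(d)
    keep[idx] <- d <= thr
  }
  if (!any(keep)) stop_empty("outlier removal removed all cells")
  m[, keep]
}

#' Gene quality filtering
#'
#' Keeps genes whose total count across cells is at least `min_total`, then
#' removes high-outlier genes whose log2(total + 1) lies strictly above
#' `median + k_mad * MAD` of the log-totals (one-sided: only unusually highly
#' expressed genes are dropped). The cell set is unchanged; `k_mad = Inf`
#' disables the outlier step.
#'
#' @param m a `CountMatrix`.
#' @param min_total minimum total count per gene (default 1).
#' @param k_mad MAD multiplier (default 3).
#' @return Filtered `CountMatrix`.
#' @export
filter_genes <- function(m, min_total = 1, k_mad = 3) {
  stopifnot(min_total >= 0)
  tot <- Matrix::rowSums(counts(m))
  keep <- tot >= min_total
  if (is.finite(k_mad)) {
    lt <- log2(tot + 1)
    thr <- stats::median(lt[keep]) + k_mad * stats::mad(lt[keep])
    keep <- keep & lt <= thr
  }
  if (!any(keep)) stop_empty("gene filtering removed all genes")
  m[keep, ]
}

#' Exclude named genes
#'
#' Removes the listed genes from the matrix, e.g. dominant hormone markers
#' (INS, GCG, SST, PPY, GHRL) that would otherwise drive the clustering by
#' themselves. Unknown names are ignored with a warning.
#'
#' @param m a `CountMatrix`.
#' @param names character vector of gene ids to drop.
#' @return `CountMatrix` without the named genes.
#' @export
exclude_genes <- function(m, names) {
  if (length(names) == 0) return(m)
  unknown <- setdiff(names, gene_ids(m))
  if (length(unknown))
    warning("genes not in matrix, ignored: ", paste(unknown, collapse = ", "))
  keep <- !(gene_ids(m) %in% names)
  if (!any(keep)) stop_empty("gene exclusion removed all genes")
  m[keep, ]
}
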