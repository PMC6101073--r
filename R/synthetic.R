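#' Specification of a synthetic cell-type mixture
#'
#' Describes a mixture of FACS-sorted-like cell types: each type carries a
#' set of marker genes expressed `marker_fold` times above the baseline
#' mean; `similarity` is the fraction of each type's markers drawn from a
#' pool shared by all types, so 0 gives disjoint marker sets (highly
#' dissimilar types) and values near 1 give nearly identical types. Counts
#' are negative binomial with per-gene zero inflation whose detection
#' probability increases with the mean (logistic in log2 mean with slope
#' `dropout_logit_slope` and midpoint 0.05), emulating the heavy sparsity of
#' UMI data.
#'
#' @param n_types number of cell types.
#' @param cells_per_type integer vector of cells per type (e.g. c(875, 125)
#'   for a 7:1 mixture of 1,000 cells).
#' @param n_genes total number of genes.
#' @param n_markers_per_type markers per type.
#' @param marker_fold fold-change of markers over baseline (> 1).
#' @param similarity marker-set overlap between type pairs, in \[0, 1\].
#' @param baseline_mean negative-binomial mean of background genes.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param dropout_logit_slope slope of the logistic detection model.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return A `MixtureSpec`.
#' @export
mixture_spec <- function(n_types = 2, cells_per_type = c(500, 500),
                         n_genes = 2000, n_markers_per_type = 50,
                         marker_fold = 20, similarity = 0,
                         baseline_mean = 0.3, dispersion = 0.5,
                         dropout_logit_slope = 1, seed = 1) {
  stopifnot(n_types >= 1, length(cells_per_type) == n_types,
            all(cells_per_type >= 1), marker_fold > 1,
            similarity >= 0, similarity <= 1,
            baseline_mean > 0, dispersion > 0)
  if (n_markers_per_type * n_types > n_genes)
    stop_value("infeasible marker allocation: ", n_markers_per_type, " x ",
               n_types, " markers > ", n_genes, " genes")
  structure(list(n_types = n_types, cells_per_type = as.integer(cells_per_type),
                 n_genes = as.integer(n_genes),
                 n_markers_per_type = as.integer(n_markers_per_type),
                 marker_fold = marker_fold, similarity = similarity,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 dropout_logit_slope = dropout_logit_slope,
                 seed = as.integer(seed)),
            class = "MixtureSpec")
}

#' Generate a synthetic cell-type mixture
#'
#' Draws a UMI-like count matrix and its ground-truth type labels from a
#' [mixture_spec()]. Marker allocation: `round(similarity *
#' n_markers_per_type)` genes form a pool shared by every type; each type
#' additionally receives its own disjoint unique markers, so any two types
#' overlap in exactly the shared fraction. Counts are NB(mu, size =
#' 1/dispersion) with mu = baseline_mean for background genes and
#' baseline_mean * marker_fold for the cell's own type markers, thinned by
#' an independent detection draw with probability
#' plogis(slope * (log2(mu) - log2(0.05))).
#'
#' @param spec a `MixtureSpec`.
#' @return List with `matrix` (a `CountMatrix`, unit "umi"), `truth` (named
#'   vector cell id -> "type1", "type2", ...), and `markers` (list of marker
#'   gene ids per type).
#' @export
generate_mixture <- function(spec) {
  stopifnot(inherits(spec, "MixtureSpec"))
  n_shared <- round(spec$similarity * spec$n_markers_per_type)
  n_unique <- spec$n_markers_per_type - n_shared
  need <- n_shared + spec$n_types * n_unique
  if (need > spec$n_genes)
    stop_value("infeasible marker allocation: needs ", need, " genes, have ",
               spec$n_genes)
  shared <- seq_len(n_shared)
  uniq <- lapply(seq_len(spec$n_types), function(t)
    n_shared + (t - 1L) * n_unique + seq_len(n_unique))
  markers <- lapply(uniq, function(u) c(shared, u))
  n_cells <- sum(spec$cells_per_type)
  gene_names <- sprintf("gene%04d", seq_len(spec$n_genes))
  cell_names <- sprintf("cell%05d", seq_len(n_cells))
  truth <- rep(paste0("type", seq_len(spec$n_types)), spec$cells_per_type)
  names(truth) <- cell_names
  size <- 1 / spec$dispersion
  mu0 <- spec$baseline_mean
  counts <- with_seed(spec$seed, {
    blocks <- lapply(seq_len(spec$n_types), function(t) {
      nc <- spec$cells_per_type[t]
      mu <- rep(mu0, spec$n_genes)
      mu[markers[[t]]] <- mu0 * spec$marker_fold
      x <- matrix(stats::rnbinom(spec$n_genes * nc, mu = mu, size = size),
                  spec$n_genes, nc)
      p <- stats::plogis(spec$dropout_logit_slope * (log2(mu) - log2(0.05)))
      keep <- matrix(stats::rbinom(spec$n_genes * nc, 1, p), spec$n_genes, nc)
      x * keep
    })
    do.call(cbind, blocks)
  })
  m <- count_matrix(counts, gene_names, cell_names, unit = "umi")
  list(matrix = m, truth = truth,
       markers = lapply(markers, function(i) gene_names[i]))
}

#' Generate a nested three-type mixture (distant type + similar pair)
#'
#' Fixture for silhouette-driven recursive re-partitioning: type 1 carries
#' its own disjoint marker set while types 2 and 3 share most of theirs,
#' differing only in `n_unique_pair` genes each. Because pairwise distances
#' are min-max scaled globally before graph construction, the large
#' type-1-versus-rest distances compress the pair's internal contrast toward
#' zero, so modularity clustering tends to merge types 2 and 3 into one
#' cluster; re-applying the transform to that cluster alone restores the
#' contrast and the pair separates.
#'
#' @param cells_per_type integer vector of length 3.
#' @param n_genes,n_markers_per_type,marker_fold,baseline_mean,dispersion,dropout_logit_slope
#'   as in [mixture_spec()].
#' @param n_unique_pair number of markers private to each of types 2 and 3
#'   (the remaining `n_markers_per_type - n_unique_pair` are shared by the
#'   pair).
#' @param seed RNG seed.
#' @return List with `matrix`, `truth`, `markers` as in
#'   [generate_mixture()].
#' @export
generate_nested_mixture <- function(cells_per_type = c(100, 100, 100),
                                    n_genes = 2000, n_markers_per_type = 50,
                                    n_unique_pair = 8, marker_fold = 20,
                                    baseline_mean = 0.3, dispersion = 0.5,
                                    dropout_logit_slope = 1, seed = 1) {
  stopifnot(length(cells_per_type) == 3, n_unique_pair <= n_markers_per_type)
  n_shared_pair <- n_markers_per_type - n_unique_pair
  idx1 <- seq_len(n_markers_per_type)
  pair_shared <- n_markers_per_type + seq_len(n_shared_pair)
  idx2 <- c(pair_shared, max(pair_shared) + seq_len(n_unique_pair))
  idx3 <- c(pair_shared, max(idx2) + seq_len(n_unique_pair))
  if (max(idx3) > n_genes) stop_value("infeasible marker allocation")
  markers <- list(idx1, idx2, idx3)
  n_cells <- sum(cells_per_type)
  gene_names <- sprintf("gene%04d", seq_len(n_genes))
  cell_names <- sprintf("cell%05d", seq_len(n_cells))
  truth <- stats::setNames(rep(paste0("type", 1:3), cells_per_type), cell_names)
  size <- 1 / dispersion
  counts <- with_seed(seed, {
    blocks <- lapply(1:3, function(t) {
      nc <- cells_per_type[t]
      mu <- rep(baseline_mean, n_genes)
      mu[markers[[t]]] <- baseline_mean * marker_fold
      x <- matrix(stats::rnbinom(n_genes * nc, mu = mu, size = size), n_genes, nc)
      p <- stats::plogis(dropout_logit_slope * (log2(mu) - log2(0.05)))
      x * matrix(stats::rbinom(n_genes * nc, 1, p), n_genes, nc)
    })
    do.call(cbind, blocks)
  })
  list(matrix = count_matrix(counts, gene_names, cell_names, unit = "umi"),
       truth = truth, markers = lapply(markers, function(i) gene_names[i]))
}

#' Similarity tiers of a mixture spec
#'
#' Returns three copies of the spec differing only in `similarity`,
#' representing mixtures of highly dissimilar (0.0), intermediate (0.5) and
#' highly similar (0.8) cell-type pairs.
#'
#' @param spec a `MixtureSpec`.
#' @return Named list of `MixtureSpec`s: `dissimilar`, `intermediate`,
#'   `similar`.
#' @export
similarity_tiers <- function(spec) {
  tiers <- c(dissimilar = 0.0, intermediate = 0.5, similar = 0.8)
  out <- lapply(tiers, function(s) { spec$similarity <- s; spec })
  names(out) <- names(tiers)
  out
}

#' Write a synthetic mixture as a 10x-style directory
#'
#' Writes matrix.mtx/genes.tsv/barcodes.tsv plus a `truth.tsv` label file.
#'
#' @param mix result of [generate_mixture()].
#' @param dir_path output directory.
#' @export
write_mixture <- function(mix, dir_path) {
  write_10x_triplet(mix$matrix, dir_path)
  utils::write.table(data.frame(cell_id = names(mix$truth), label = mix$truth),
                     file.path(dir_path, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir_path)
}
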