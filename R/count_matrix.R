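#' Gene-by-cell count matrix
#'
#' The central container of the package: a sparse genes x cells matrix of
#' non-negative expression values together with unique gene and cell
#' identifiers. Genes play the role of "words" and cells the role of
#' "documents" in the TF-IDF analogy, so the matrix is always stored with
#' genes as rows. `unit` records whether values are UMI counts, raw read
#' counts (both integer) or RPKM-like continuous values.
#'
#' @param values numeric matrix or [Matrix::Matrix] (genes x cells),
#'   all entries >= 0; integer-valued unless `unit = "rpkm"`.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param unit one of `"umi"`, `"read_count"`, `"rpkm"`.
#' @return An object of class `CountMatrix`.
#' @examples
#' m <- count_matrix(matrix(c(1, 0, 2, 3), 2), c("g1", "g2"), c("c1", "c2"))
#' dim(m)
#' @export
count_matrix <- function(values, gene_ids, cell_ids,
                         unit = c("umi", "read_count", "rpkm")) {
  unit <- match.arg(unit)
  v <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(v) != length(gene_ids))
    stop_format("gene_ids length (", length(gene_ids), ") != number of rows (", nrow(v), ")")
  if (ncol(v) != length(cell_ids))
    stop_format("cell_ids length (", length(cell_ids), ") != number of columns (", ncol(v), ")")
  if (anyDuplicated(gene_ids)) stop_format("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop_format("duplicate cell_ids")
  if (length(v@x) && min(v@x) < 0) stop_value("negative values in count matrix")
  if (unit != "rpkm" && length(v@x) && any(abs(v@x - round(v@x)) > 1e-8))
    stop_value("non-integer values with unit '", unit, "'")
  dimnames(v) <- list(gene_ids, cell_ids)
  structure(list(values = v, unit = unit), class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' Accessors for CountMatrix
#'
#' @param x a `CountMatrix`.
#' @return `gene_ids()` / `cell_ids()` return character vectors;
#'   `counts()` the underlying sparse matrix.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(x) colnames(x$values)

#' @rdname gene_ids
#' @export
counts <- function(x) x$values

#' Subset a CountMatrix
#'
#' @param x a `CountMatrix`.
#' @param i,j gene / cell indices (any standard matrix index).
#' @param ... ignored.
#' @param drop ignored; dimensions are always kept.
#' @export
`[.CountMatrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  count_matrix(v, rownames(v), colnames(v), unit = x$unit)
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (unit: %s, %.2f%% nonzero)\n",
              nrow(x$values), ncol(x$values), x$unit,
              100 * length(x$values@x) / prod(dim(x$values))))
  invisible(x)
}

#' Read a 10x-style triplet directory
#'
#' Reads `matrix.mtx` (MatrixMarket coordinate format, 1-based indices),
#' `genes.tsv` or `features.tsv`, and `barcodes.tsv` from a directory, as
#' produced by the CellRanger pipeline. Duplicate gene symbols are
#' disambiguated with an occurrence-counter suffix; the original symbols are
#' kept in the `original_gene_ids` attribute.
#'
#' @param dir_path directory containing the three files.
#' @return A `CountMatrix` with `unit = "umi"`.
#' @export
read_10x_triplet <- function(dir_path) {
  if (!dir.exists(dir_path)) stop_input("directory not found: ", dir_path)
  mtx <- file.path(dir_path, "matrix.mtx")
  if (!file.exists(mtx)) stop_input("missing file: ", mtx)
  genes <- file.path(dir_path, "genes.tsv")
  if (!file.exists(genes)) genes <- file.path(dir_path, "features.tsv")
  if (!file.exists(genes))
    stop_input("missing file: ", file.path(dir_path, "genes.tsv"), " (or features.tsv)")
  bc <- file.path(dir_path, "barcodes.tsv")
  if (!file.exists(bc)) stop_input("missing file: ", bc)

  m <- Matrix::readMM(mtx)
  gt <- utils::read.delim(genes, header = FALSE, stringsAsFactors = FALSE)
  bt <- utils::read.delim(bc, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(gt) != nrow(m))
    stop_format("genes file has ", nrow(gt), " lines but MTX header declares ",
                nrow(m), " rows")
  if (nrow(bt) != ncol(m))
    stop_format("barcodes file has ", nrow(bt), " lines but MTX header declares ",
                ncol(m), " columns")
  # 10x genes.tsv: column 1 = Ensembl id, column 2 (if present) = symbol
  sym <- if (ncol(gt) >= 2) gt[[2]] else gt[[1]]
  ids <- make.unique(as.character(sym), sep = ".")
  bcs <- make.unique(as.character(bt[[1]]), sep = ".")
  out <- count_matrix(m, ids, bcs, unit = "umi")
  attr(out, "original_gene_ids") <- as.character(sym)
  out
}

#' Write a CountMatrix as a 10x-style triplet directory
#'
#' Inverse of [read_10x_triplet()]: writes `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv` so that reading the directory back reproduces the matrix.
#'
#' @param x a `CountMatrix`.
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_10x_triplet <- function(x, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$values, file.path(dir_path, "matrix.mtx"))
  utils::write.table(data.frame(id = gene_ids(x), symbol = gene_ids(x)),
                     file.path(dir_path, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(cell_ids(x), file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

#' Read a dense CSV/TSV count table
#'
#' @param path path to a rectangular delimited table.
#' @param has_header logical; first row holds cell (or gene) ids.
#' @param genes_in_rows logical; if `FALSE` the table is transposed after
#'   reading so that genes always end up as rows.
#' @param unit value unit, see [count_matrix()].
#' @param sep field separator; guessed from the file extension by default.
#' @return A `CountMatrix`.
#' @export
read_dense_csv <- function(path, has_header = TRUE, genes_in_rows = TRUE,
                           unit = c("umi", "read_count", "rpkm"), sep = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1) stop_format("ragged rows in ", path)
  df <- utils::read.table(path, header = has_header, sep = sep,
                          row.names = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_format("non-numeric or missing entries in ", path)
  if (any(m < 0)) stop_value("negative value in ", path)
  if (!genes_in_rows) m <- t(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("cell", seq_len(ncol(m)))
  count_matrix(m, rownames(m), colnames(m), unit = unit)
}

#' Read per-cell ground-truth labels
#'
#' @param path two-column headerless TSV: cell id, class label.
#' @return Named character vector mapping cell id to label; empty for an
#'   empty file.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_format("expected two columns in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_format("duplicate cell id in ", path, ": ", ids[anyDuplicated(ids)])
  stats::setNames(as.character(df[[2]]), ids)
}

#' Write / read cluster assignments as TSV
#'
#' Two-column TSV (cell_id, cluster_id) used by the CLI.
#'
#' @param assignment a `ClusterAssignment`.
#' @param path output path.
#' @return `path` (write) or a named integer vector (read), invisibly for
#'   the writer.
#' @export
write_assignments <- function(assignment, path) {
  utils::write.table(data.frame(cell_id = names(assignment$labels),
                                cluster_id = assignment$labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$cluster_id), df$cell_id)
}
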