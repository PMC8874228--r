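#' Gene-by-cell count matrix with per-cell metadata
#'
#' The universal input of the pipeline: a sparse gene x cell matrix of raw
#' integer counts plus a per-cell metadata table. Per-cell QC statistics
#' (`n_features`, `total_counts`, `mt_fraction`) are computed at construction
#' from the counts themselves, so they are always consistent with `values`.
#'
#' @param values gene x cell matrix of nonnegative integers (dense or sparse;
#'   coerced to `dgCMatrix`). Must carry row and column names unless
#'   `gene_ids` / `cell_ids` are given.
#' @param gene_ids unique gene identifiers (defaults to `rownames(values)`).
#' @param cell_ids unique cell barcodes (defaults to `colnames(values)`).
#' @param cell_meta data.frame of per-cell annotations (one row per cell, in
#'   the column order of `values`). Typical columns: `condition`, `genotype`,
#'   `day_or_week`. May be `NULL`.
#' @param mt_pattern regular expression identifying mitochondrial gene names
#'   (case-insensitive), used to compute `mt_fraction`.
#' @return an object of class `count_matrix`: a list with elements `values`
#'   (dgCMatrix), `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values), cell_meta = NULL,
                         mt_pattern = "^MT-") {
  if (!inherits(values, "sparseMatrix"))
    values <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
  values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell identifiers are required")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    stop("identifier length does not match matrix dimensions")
  x <- values@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be nonnegative integers")
  dimnames(values) <- list(gene_ids, cell_ids)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(barcode = cell_ids, stringsAsFactors = FALSE)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != length(cell_ids))
      stop("cell_meta rows must match number of cells")
    cell_meta$barcode <- cell_ids
  }
  rownames(cell_meta) <- cell_ids
  cell_meta$n_features <- Matrix::colSums(values > 0)
  cell_meta$total_counts <- Matrix::colSums(values)
  is_mt <- grepl(mt_pattern, gene_ids, ignore.case = TRUE)
  mt_counts <- if (any(is_mt)) Matrix::colSums(values[is_mt, , drop = FALSE]) else 0
  cell_meta$mt_fraction <- ifelse(cell_meta$total_counts > 0,
                                  mt_counts / cell_meta$total_counts, 0)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells\n",
              length(x$gene_ids), length(x$cell_ids)))
  if (!is.null(x$cell_meta$condition))
    cat("conditions:", paste(unique(x$cell_meta$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Log-normalized expression matrix
#'
#' Holds library-size log-normalized values together with provenance
#' (scale factor and log base) so downstream statistics are auditable.
#' Zeros are preserved exactly: a normalized value is 0 iff the raw count was 0.
#'
#' @param values gene x cell matrix of normalized values (sparse).
#' @param cell_meta per-cell metadata carried over from the source counts.
#' @param provenance list with at least `scale_factor` and `log_base`.
#' @return object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, cell_meta, provenance) {
  structure(list(values = values,
                 gene_ids = rownames(values), cell_ids = colnames(values),
                 cell_meta = cell_meta, provenance = provenance),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (scale %s, log %s)\n",
              nrow(x$values), ncol(x$values),
              format(x$provenance$scale_factor), x$provenance$log_base))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' Binarized marker matrix
#'
#' A gene x cell-type table with 1 where the gene marks that (sub)type, plus a
#' mapping from subtypes to generic classes (e.g. dopaminergic-neuron
#' subtypes to "mDN", radial glia to "glia"). Cell-type assignment scores
#' cluster markers against the 1-entries of this table.
#'
#' @param mat binary gene x subtype matrix (rownames = genes, colnames =
#'   subtype names, entries 0/1).
#' @param class_map named character vector mapping each subtype (names) to its
#'   generic class (values). Defaults to the identity mapping.
#' @return object of class `marker_matrix`.
#' @export
marker_matrix <- function(mat, class_map = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("marker matrix needs gene rownames and type colnames")
  if (!all(mat %in% c(0, 1))) stop("marker matrix entries must be 0/1")
  if (is.null(class_map)) {
    class_map <- stats::setNames(colnames(mat), colnames(mat))
  } else {
    missing <- setdiff(colnames(mat), names(class_map))
    if (length(missing))
      stop("class_map must cover every subtype; missing: ",
           paste(missing, collapse = ", "))
  }
  structure(list(mat = mat, class_map = class_map), class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d genes x %d subtypes (%d generic classes)\n",
              nrow(x$mat), ncol(x$mat), length(unique(x$class_map))))
  invisible(x)
}

# internal: dense numeric submatrix of a sparse container
.dense_values <- function(m, genes = NULL, cells = NULL) {
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  as.matrix(v)
}
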