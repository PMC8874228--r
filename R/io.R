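#' Write a dataset as Matrix Market + TSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells), `features.tsv`, `barcodes.tsv` and
#' `metadata.tsv` (barcode, condition, genotype, day_or_week) into `dir`.
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cm$values, file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(dir, "features.tsv"))
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  keep <- intersect(c("barcode", "condition", "genotype", "day_or_week"),
                    colnames(cm$cell_meta))
  utils::write.table(cm$cell_meta[, keep, drop = FALSE],
                     file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and (optionally) `metadata.tsv`.
#' @return a [count_matrix()].
#' @export
read_dataset <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- if (file.exists(meta_path))
    utils::read.table(meta_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = "character")
  else NULL
  rownames(m) <- genes
  colnames(m) <- cells
  count_matrix(m, cell_meta = meta)
}

#' Write a binarized marker matrix as CSV
#'
#' Rows are genes, columns are (sub)types, values 0/1. The subtype-to-class
#' mapping is written alongside when `class_file` is given.
#'
#' @param mm a [marker_matrix()].
#' @param file output CSV path.
#' @param class_file optional CSV path for the mapping (subtype, class).
#' @return `file`, invisibly.
#' @export
write_marker_matrix <- function(mm, file, class_file = NULL) {
  stopifnot(inherits(mm, "marker_matrix"))
  utils::write.csv(as.data.frame(mm$mat), file, quote = FALSE)
  if (!is.null(class_file))
    utils::write.csv(data.frame(subtype = names(mm$class_map),
                                class = unname(mm$class_map)),
                     class_file, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a binarized marker matrix from CSV
#'
#' @param file CSV with gene rownames and 0/1 entries per type column.
#' @param class_file optional mapping CSV (subtype, class); identity
#'   mapping when absent.
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(file, class_file = NULL) {
  mat <- as.matrix(utils::read.csv(file, row.names = 1, check.names = FALSE))
  cmap <- NULL
  if (!is.null(class_file)) {
    df <- utils::read.csv(class_file, stringsAsFactors = FALSE)
    cmap <- stats::setNames(df$class, df$subtype)
  }
  marker_matrix(mat, cmap)
}

#' Write simulation ground truth as JSON
#'
#' @param truth truth list from [simulate_dataset()].
#' @param file output JSON path.
#' @return `file`, invisibly.
#' @export
write_truth <- function(truth, file) {
  out <- truth[c("true_type", "true_latent_time", "genotype", "condition",
                 "de_marker_overlap", "doublet_flags")]
  out$de_gene_truth <- truth$de_gene_truth
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
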