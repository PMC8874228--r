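#' Mutual genes across datasets
#'
#' Exact intersection of gene names across two or more datasets, sorted
#' deterministically.
#'
#' @param datasets list of `count_matrix` / `normalized_matrix` objects or
#'   plain gene-name vectors.
#' @return sorted character vector of shared genes; error if empty.
#' @export
mutual_genes <- function(datasets) {
  if (length(datasets) < 2) stop("need at least 2 datasets")
  ids <- lapply(datasets, function(d)
    if (is.character(d)) d else d$gene_ids)
  common <- Reduce(intersect, ids)
  if (length(common) == 0) stop("empty gene intersection")
  sort(common)
}

#' Average expression profile of a cell group
#'
#' Arithmetic per-gene mean of the normalized values over the given cells
#' (or, by flag, of the de-logged values).
#'
#' @param nm a [normalized_matrix()].
#' @param cells cell ids to average over (default: all).
#' @param delog average `expm1(value)` instead of the log values.
#' @return named numeric vector, one mean per gene.
#' @export
average_profile <- function(nm, cells = NULL, delog = FALSE) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (is.null(cells)) cells <- nm$cell_ids
  if (length(cells) == 0) stop("empty cell group")
  v <- nm$values[, cells, drop = FALSE]
  if (delog) v <- expm1(v)
  stats::setNames(Matrix::rowMeans(v), nm$gene_ids)
}

#' Stage a query profile against reference weeks
#'
#' Correlates a query sample's average transcriptome with each reference
#' week's average transcriptome (on an identical mutual-gene list) and
#' assigns the week attaining the maximum coefficient. This is the
#' developmental-staging computation: an organoid's transcriptome is placed
#' at the embryonic week it most resembles.
#'
#' @param query named per-gene mean vector.
#' @param reference gene x week matrix of per-week mean vectors (column
#'   names = week labels).
#' @param method `"pearson"` or `"spearman"`.
#' @return object of class `staging_profile`: list with `r` (named per-week
#'   coefficients), `assigned_week`, `tie` flag, `method`, `n_common_genes`.
#' @export
stage_by_correlation <- function(query, reference,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(names(query)) || is.null(rownames(reference)))
    stop("query and reference must carry gene names")
  if (!identical(names(query), rownames(reference)))
    stop("query and reference must be on the identical mutual-gene list")
  if (length(query) < 2) stop("need more than one common gene")
  if (stats::sd(query) == 0) stop("zero-variance query: coefficient undefined")
  if (any(apply(reference, 2, stats::sd) == 0))
    stop("zero-variance reference column: coefficient undefined")
  r <- apply(reference, 2, function(ref) stats::cor(query, ref, method = method))
  best <- max(r)
  winners <- which(r >= best - 1e-12)
  structure(list(r = r, assigned_week = colnames(reference)[winners[1]],
                 tie = length(winners) > 1, method = method,
                 n_common_genes = length(query)),
            class = "staging_profile")
}

#' @export
print.staging_profile <- function(x, ...) {
  cat(sprintf("staging_profile (%s, %d genes): assigned %s%s\n",
              x$method, x$n_common_genes, x$assigned_week,
              if (x$tie) " [tie]" else ""))
  print(round(x$r, 3))
  invisible(x)
}

#' Cross-region similarity screen
#'
#' Pairwise Spearman correlation of per-dataset average profiles, with a
#' same-region call where the coefficient exceeds the threshold (default
#' 0.7, the screening value used to separate midbrain from cortex).
#'
#' @param profiles gene x dataset matrix of average profiles on mutual
#'   genes.
#' @param threshold same-region call threshold on rho.
#' @return list with `rho` (dataset x dataset matrix) and `similar`
#'   (logical matrix, `rho > threshold`, diagonal `TRUE`).
#' @export
region_similarity_screen <- function(profiles, threshold = 0.7) {
  if (ncol(profiles) < 2) stop("need at least 2 profiles")
  if (any(apply(profiles, 2, stats::sd) == 0))
    stop("zero-variance profile: coefficient undefined")
  rho <- stats::cor(profiles, method = "spearman")
  similar <- rho > threshold
  diag(similar) <- TRUE
  list(rho = rho, similar = similar)
}
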