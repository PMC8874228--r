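#' Quality-control thresholds
#'
#' The cell-level filters applied to the organoid datasets before any
#' analysis: a ceiling on detected features (probable doublets/multiplets),
#' a timepoint-dependent floor on detected features (low-quality cells and
#' empty droplets), and a cap on the mitochondrial count fraction. The
#' defaults are the study's values: ceiling 2,500, floor 100 for day-35 and
#' 200 for day-70 datasets, mitochondrial fraction at most 0.30, and
#' library-size scale factor 10,000.
#'
#' @param max_features remove cells with more detected genes than this.
#' @param min_features either a single floor, or a named vector keyed by the
#'   `day_or_week` metadata value (e.g. `c("35" = 100, "70" = 200)`); cells
#'   whose key is absent fall back to `min_features_default`.
#' @param min_features_default fallback floor for datasets without a key.
#' @param max_mt_fraction remove cells with mitochondrial fraction strictly
#'   above this value ("above 30%" is read as `> 0.30`).
#' @param scale_factor target per-cell transcript total for normalization.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_features = 2500,
                          min_features = c("35" = 100, "70" = 200),
                          min_features_default = 100,
                          max_mt_fraction = 0.30,
                          scale_factor = 10000) {
  if (max_mt_fraction <= 0 || max_mt_fraction > 1)
    stop("max_mt_fraction must be in (0, 1]")
  if (any(min_features >= max_features))
    stop("min_features must be below max_features")
  structure(list(max_features = max_features, min_features = min_features,
                 min_features_default = min_features_default,
                 max_mt_fraction = max_mt_fraction,
                 scale_factor = scale_factor),
            class = "qc_thresholds")
}

# internal: per-cell feature floor resolved from metadata
.min_features_for <- function(t, meta) {
  mf <- t$min_features
  if (is.null(names(mf)) || length(mf) == 1L && is.null(names(mf)))
    return(rep(mf[[1]], nrow(meta)))
  key <- as.character(meta$day_or_week)
  out <- unname(mf[key])
  out[is.na(out)] <- t$min_features_default
  out
}

#' Filter cells on feature counts and mitochondrial fraction
#'
#' Retains exactly the cells with
#' `min_features <= n_features <= max_features` and
#' `mt_fraction <= max_mt_fraction`; the order of surviving cells is
#' preserved. A per-rule removal log is attached as attribute `"qc_log"`.
#'
#' @param m a [count_matrix()].
#' @param t a [qc_thresholds()].
#' @return the filtered `count_matrix`.
#' @export
filter_cells <- function(m, t = qc_thresholds()) {
  stopifnot(inherits(m, "count_matrix"))
  meta <- m$cell_meta
  floor_per_cell <- .min_features_for(t, meta)
  low <- meta$n_features < floor_per_cell
  high <- meta$n_features > t$max_features
  mt <- meta$mt_fraction > t$max_mt_fraction
  keep <- !(low | high | mt)
  log <- list(cells_in = nrow(meta),
              removed_low_features = sum(low),
              removed_high_features = sum(high),
              removed_mt_fraction = sum(mt & !low & !high),
              cells_out = sum(keep))
  if (!any(keep)) {
    rule <- names(which.max(c(low_features = sum(low),
                              high_features = sum(high),
                              mt_fraction = sum(mt))))
    stop("empty result: all cells removed by QC (binding rule: ", rule, ")")
  }
  out <- count_matrix(m$values[, keep, drop = FALSE],
                      cell_meta = meta[keep, setdiff(colnames(meta),
                        c("barcode", "n_features", "total_counts", "mt_fraction")),
                        drop = FALSE])
  attr(out, "qc_log") <- log
  out
}

#' Remove mitochondrial genes
#'
#' Drops all genes whose name matches the mitochondrial prefix. Applied
#' after [filter_cells()]: the `mt_fraction` used for filtering is computed
#' on the pre-removal matrix, and is carried over unchanged here so the QC
#' decision remains auditable.
#'
#' @param m a [count_matrix()].
#' @param pattern regular expression for mitochondrial gene names
#'   (case-insensitive).
#' @return `count_matrix` without the matching genes.
#' @export
drop_mt_genes <- function(m, pattern = "^MT-") {
  stopifnot(inherits(m, "count_matrix"))
  is_mt <- grepl(pattern, m$gene_ids, ignore.case = TRUE)
  if (!any(is_mt)) return(m)
  frozen_mt <- m$cell_meta$mt_fraction
  out <- count_matrix(m$values[!is_mt, , drop = FALSE],
                      cell_meta = m$cell_meta[, setdiff(colnames(m$cell_meta),
                        c("barcode", "n_features", "total_counts", "mt_fraction")),
                        drop = FALSE])
  out$cell_meta$mt_fraction <- frozen_mt  # pre-removal value, by contract
  out
}

#' Library-size log-normalization
#'
#' `value(g, c) = ln(1 + count(g, c) * scale_factor / total_counts(c))`
#' (natural log), the standard per-cell normalization to a fixed transcript
#' total. Zeros map to zeros, so sparsity is preserved, and per cell the
#' de-logged values satisfy `sum(expm1(value)) == scale_factor`.
#'
#' @param m a [count_matrix()] that has already passed QC.
#' @param t a [qc_thresholds()] (only `scale_factor` is used).
#' @return a [normalized_matrix()].
#' @export
lognormalize <- function(m, t = qc_thresholds()) {
  stopifnot(inherits(m, "count_matrix"))
  tot <- m$cell_meta$total_counts
  if (any(tot <= 0))
    stop("cells with zero total counts present; run filter_cells() first")
  v <- m$values
  # scale the nonzero entries column-wise, then log1p
  percell <- t$scale_factor / tot
  v@x <- log1p(v@x * rep.int(percell, diff(v@p)))
  normalized_matrix(v, m$cell_meta,
                    provenance = list(source = "count_matrix",
                                      scale_factor = t$scale_factor,
                                      log_base = "e"))
}
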