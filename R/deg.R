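#' Differential-expression filter settings
#'
#' The study's DEG filters: absolute log2 fold change above 0.25, adjusted
#' p below 0.05, and detection in at least 10% of cells in one group.
#'
#' @param min_abs_log2fc minimum `|log2FC|` for a gene to be tested.
#' @param alpha adjusted-p significance threshold.
#' @param min_pct minimum detection fraction in the better-detected group.
#' @return object of class `deg_filter`.
#' @export
deg_filter <- function(min_abs_log2fc = 0.25, alpha = 0.05, min_pct = 0.1) {
  stopifnot(min_abs_log2fc >= 0, alpha > 0, alpha <= 1,
            min_pct >= 0, min_pct <= 1)
  structure(list(min_abs_log2fc = min_abs_log2fc, alpha = alpha,
                 min_pct = min_pct), class = "deg_filter")
}

#' Two-group Wilcoxon differential expression
#'
#' The MUT-vs-WT contrast of the pipeline: genes are pre-filtered to those
#' detected in at least `min_pct` of either group and with
#' `|log2FC| >= min_abs_log2fc` (log2FC = log2 ratio of pseudocounted
#' de-logged group means, group 1 first), then tested with a two-sided
#' Wilcoxon rank-sum (tie-corrected normal approximation with continuity
#' correction; exact enumeration when `n1 + n2 <= 20`). Bonferroni
#' adjustment is over all genes in the matrix by default (the behavior of
#' the workflow the thresholds come from), or over the tested subset by
#' flag.
#'
#' @param nm a [normalized_matrix()].
#' @param cells1,cells2 disjoint cell-id vectors (each >= 3 cells);
#'   group 1 is conventionally the mutant.
#' @param f a [deg_filter()].
#' @param adjust_over `"all"` (Bonferroni over all genes in `nm`) or
#'   `"tested"` (over the pre-filtered genes only).
#' @return data.frame of DEG records sorted by `p_adj` then `|log2fc|`:
#'   gene, log2fc, p_raw, p_adj, pct1, pct2, n1, n2. The number of tests
#'   used for adjustment is attached as attribute `"n_tests"`.
#' @export
deg_wilcoxon <- function(nm, cells1, cells2, f = deg_filter(),
                         adjust_over = c("all", "tested")) {
  stopifnot(inherits(nm, "normalized_matrix"))
  adjust_over <- match.arg(adjust_over)
  if (length(intersect(cells1, cells2)) > 0) stop("groups must be disjoint")
  if (length(cells1) < 3 || length(cells2) < 3)
    stop("each group needs at least 3 cells")
  x <- .dense_values(nm, cells = c(cells1, cells2))
  idx1 <- seq_along(cells1)
  idx2 <- length(cells1) + seq_along(cells2)
  lfc <- .log2fc(x, idx1, idx2)
  pct1 <- rowMeans(x[, idx1, drop = FALSE] > 0)
  pct2 <- rowMeans(x[, idx2, drop = FALSE] > 0)
  tested <- pmax(pct1, pct2) >= f$min_pct & abs(lfc) >= f$min_abs_log2fc
  if (!any(tested)) {
    warning("no genes pass the pre-filter")
    out <- data.frame(gene = character(), log2fc = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      pct1 = numeric(), pct2 = numeric(),
                      n1 = integer(), n2 = integer())
    attr(out, "n_tests") <- 0L
    return(out)
  }
  xt <- x[tested, , drop = FALSE]
  if (length(idx1) + length(idx2) <= 20) {
    p <- apply(xt, 1, function(v) .ranksum_p_exact(v[idx1], v[idx2]))
  } else {
    p <- .ranksum_p_approx(xt, idx1, idx2)
  }
  m <- if (adjust_over == "all") nrow(x) else sum(tested)
  out <- data.frame(gene = rownames(x)[tested],
                    log2fc = lfc[tested], p_raw = p,
                    p_adj = pmin(p * m, 1),
                    pct1 = pct1[tested], pct2 = pct2[tested],
                    n1 = length(cells1), n2 = length(cells2),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_adj, -abs(out$log2fc), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tests") <- m
  out
}

#' Significant genes from a DEG table
#'
#' @param tab output of [deg_wilcoxon()].
#' @param alpha adjusted-p threshold.
#' @return character vector of significant gene names.
#' @export
deg_significant <- function(tab, alpha = 0.05) {
  tab$gene[tab$p_adj < alpha]
}

#' Overlap accounting for named DEG sets
#'
#' Venn arithmetic over two or more gene sets: per-set sizes, all pairwise
#' intersection sizes, per-set exclusive counts (members of no other set),
#' and the size of the common intersection.
#'
#' @param deg_sets named list of character vectors (>= 2 sets).
#' @return list with `sizes`, `pairwise` (matrix of intersection sizes),
#'   `exclusive`, `common_all`.
#' @export
deg_set_accounting <- function(deg_sets) {
  if (length(deg_sets) < 2) stop("need at least 2 sets")
  deg_sets <- lapply(deg_sets, unique)
  nm <- names(deg_sets)
  sizes <- vapply(deg_sets, length, integer(1))
  pw <- outer(nm, nm, Vectorize(function(a, b)
    length(intersect(deg_sets[[a]], deg_sets[[b]]))))
  dimnames(pw) <- list(nm, nm)
  excl <- vapply(nm, function(a) {
    others <- unique(unlist(deg_sets[setdiff(nm, a)]))
    length(setdiff(deg_sets[[a]], others))
  }, integer(1))
  list(sizes = sizes, pairwise = pw, exclusive = excl,
       common_all = length(Reduce(intersect, deg_sets)))
}

#' Cellular composition per condition
#'
#' Counts and percentages of each cell type within each condition; the
#' percentages sum to 100 per condition (rounding is left to the caller's
#' report layer).
#'
#' @param cell_types per-cell type labels.
#' @param conditions per-cell condition labels (same length).
#' @return data.frame (condition, type, count, percent) of class
#'   `composition_table`.
#' @export
composition <- function(cell_types, conditions) {
  if (length(cell_types) != length(conditions))
    stop("cell_types and conditions must align")
  tab <- table(condition = conditions, type = cell_types)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("condition", "type", "count")
  tot <- stats::ave(df$count, df$condition, FUN = sum)
  df$percent <- 100 * df$count / tot
  class(df) <- c("composition_table", class(df))
  df
}

#' Kruskal-Wallis test with the study's star labels
#'
#' Tie-corrected H statistic with a chi-squared p on `groups - 1` degrees of
#' freedom, via [stats::kruskal.test()]. When every value in every group is
#' identical the test is degenerate and `H = 0, p = 1` is returned.
#'
#' @param values list of numeric vectors, one per group (>= 2 groups).
#' @return list with `H`, `df`, `p`, `stars`.
#' @export
kruskal_wallis_by_group <- function(values) {
  if (length(values) < 2) stop("need at least 2 groups")
  if (any(vapply(values, length, integer(1)) < 1))
    stop("every group needs at least one value")
  all_v <- unlist(values)
  if (length(unique(all_v)) == 1L)
    return(list(H = 0, df = length(values) - 1L, p = 1, stars = "ns"))
  kt <- stats::kruskal.test(values)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, stars = p_stars(kt$p.value))
}
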