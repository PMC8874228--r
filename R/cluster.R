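#' Louvain community detection on the cell graph
#'
#' Multi-level modularity optimization at the given resolution (default 0.5,
#' the study's setting), deterministic under the seed. Cluster ids are
#' relabeled contiguously from 0 in order of decreasing size.
#'
#' @param g weighted undirected graph from [knn_graph()].
#' @param resolution resolution parameter of the modularity objective.
#' @param seed RNG seed.
#' @return object of class `cluster_labels`: list with `cluster` (named
#'   integer vector, 0-based), `resolution`, `modularity`, `seed`.
#' @export
louvain_cluster <- function(g, resolution = 0.5, seed = 0L) {
  if (!igraph::is_igraph(g) || igraph::vcount(g) == 0)
    stop("empty graph")
  if (resolution <= 0) stop("resolution must be > 0")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  new_id <- stats::setNames(seq_along(sizes) - 1L,
                            names(sort(sizes, decreasing = TRUE)))
  lab <- unname(new_id[as.character(memb)])
  names(lab) <- igraph::V(g)$name
  structure(list(cluster = lab, resolution = resolution,
                 modularity = igraph::modularity(g, memb,
                   weights = igraph::E(g)$weight),
                 seed = seed),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("cluster_labels: %d cells, %d clusters (resolution %g, modularity %.3f)\n",
              length(x$cluster), length(unique(x$cluster)),
              x$resolution, x$modularity))
  invisible(x)
}

#' Merge over-split clusters
#'
#' Formalizes the manual merge of adjacent, near-identical clusters: a pair
#' is merged when its centroid distance falls below the given quantile of
#' all inter-centroid distances AND the Jaccard overlap of the two clusters'
#' top marker lists is at least `jaccard_min`. Merging is transitive;
#' surviving clusters are relabeled contiguously from 0 (decreasing size).
#'
#' @param labels a `cluster_labels`.
#' @param e the `embedding` the clusters live in.
#' @param markers_per_cluster named list (by cluster id) of marker gene
#'   vectors, e.g. from [rank_cluster_markers()].
#' @param centroid_quantile quantile of inter-centroid distances below which
#'   a pair counts as "close".
#' @param jaccard_min minimum marker-list Jaccard overlap.
#' @return relabeled `cluster_labels`.
#' @export
merge_overclustered <- function(labels, e, markers_per_cluster,
                                centroid_quantile = 0.1, jaccard_min = 0.5) {
  stopifnot(inherits(labels, "cluster_labels"), inherits(e, "embedding"))
  ids <- sort(unique(labels$cluster))
  if (length(ids) < 2) return(labels)
  cent <- t(vapply(ids, function(cid)
    colMeans(e$coordinates[labels$cluster == cid, , drop = FALSE]),
    numeric(ncol(e$coordinates))))
  d <- as.matrix(stats::dist(cent))
  dvec <- d[upper.tri(d)]
  thr <- stats::quantile(dvec, centroid_quantile)
  merge_graph <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a >= b) next
    ma <- markers_per_cluster[[as.character(ids[a])]]
    mb <- markers_per_cluster[[as.character(ids[b])]]
    if (is.null(ma) || is.null(mb)) next
    jac <- length(intersect(ma, mb)) / max(length(union(ma, mb)), 1)
    if (d[a, b] < thr && jac >= jaccard_min)
      merge_graph <- igraph::add_edges(merge_graph, c(a, b))
  }
  comp <- igraph::components(merge_graph)$membership
  merged <- comp[match(labels$cluster, ids)]
  sizes <- table(merged)
  new_id <- stats::setNames(seq_along(sizes) - 1L,
                            names(sort(sizes, decreasing = TRUE)))
  labels$cluster <- stats::setNames(unname(new_id[as.character(merged)]),
                                    names(labels$cluster))
  labels
}

#' Rank marker genes per cluster
#'
#' One-vs-rest Wilcoxon rank-sum per gene per cluster on the normalized
#' values. Only genes up-regulated in the cluster (positive log2 fold
#' change of pseudocounted de-logged means) are kept, ranked by ascending p
#' then descending log2FC (gene name as the final tie-break).
#'
#' @param nm a [normalized_matrix()].
#' @param labels a `cluster_labels` on the same cells.
#' @param top_n markers to keep per cluster.
#' @param min_cells clusters below this size are skipped with a warning.
#' @return named list (by cluster id) of ordered gene name vectors.
#' @export
rank_cluster_markers <- function(nm, labels, top_n = 100, min_cells = 3) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(labels, "cluster_labels"))
  lab <- labels$cluster[nm$cell_ids]
  x <- .dense_values(nm)
  out <- list()
  for (cid in sort(unique(lab))) {
    in_cl <- which(lab == cid)
    if (length(in_cl) < min_cells) {
      warning("cluster ", cid, " has fewer than ", min_cells,
              " cells; skipped")
      out[[as.character(cid)]] <- character()
      next
    }
    res <- .ranksum_table(x, in_cl, setdiff(seq_along(lab), in_cl))
    res <- res[res$log2fc > 0, , drop = FALSE]
    res <- res[order(res$p_raw, -res$log2fc, res$gene), , drop = FALSE]
    out[[as.character(cid)]] <- utils::head(res$gene, top_n)
  }
  out
}

#' Assign cell types to clusters from a binarized marker matrix
#'
#' For every cluster, each candidate generic class is scored by the number
#' of the cluster's marker genes that are 1 in the marker matrix, combined
#' over the class's subtypes (sum by default, max by option). The class with
#' the highest score is assigned; ties go to the lexicographically first
#' class name and set the ambiguity flag; a cluster with all-zero scores is
#' assigned `"unknown"`.
#'
#' @param markers_per_cluster named list of marker gene vectors per cluster.
#' @param mm a [marker_matrix()].
#' @param combine how subtype scores merge into a generic-class score.
#' @return data.frame (cluster, type, score, ambiguous) with the full
#'   class-score matrix attached as attribute `"scores"`.
#' @export
assign_types <- function(markers_per_cluster, mm, combine = c("sum", "max")) {
  stopifnot(inherits(mm, "marker_matrix"))
  combine <- match.arg(combine)
  classes <- sort(unique(mm$class_map))
  rows <- lapply(names(markers_per_cluster), function(cid) {
    mk <- intersect(markers_per_cluster[[cid]], rownames(mm$mat))
    sub_score <- if (length(mk))
      colSums(mm$mat[mk, , drop = FALSE]) else
      stats::setNames(rep(0, ncol(mm$mat)), colnames(mm$mat))
    cls_score <- vapply(classes, function(cl) {
      s <- sub_score[mm$class_map[colnames(mm$mat)] == cl]
      if (combine == "sum") sum(s) else max(s)
    }, numeric(1))
    best <- max(cls_score)
    if (best == 0) {
      data.frame(cluster = cid, type = "unknown", score = 0,
                 ambiguous = FALSE, stringsAsFactors = FALSE)
    } else {
      winners <- classes[cls_score == best]
      data.frame(cluster = cid, type = sort(winners)[1], score = best,
                 ambiguous = length(winners) > 1, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  score_mat <- t(vapply(names(markers_per_cluster), function(cid) {
    mk <- intersect(markers_per_cluster[[cid]], rownames(mm$mat))
    sub_score <- if (length(mk))
      colSums(mm$mat[mk, , drop = FALSE]) else
      stats::setNames(rep(0, ncol(mm$mat)), colnames(mm$mat))
    vapply(classes, function(cl) {
      s <- sub_score[mm$class_map[colnames(mm$mat)] == cl]
      if (combine == "sum") sum(s) else max(s)
    }, numeric(1))
  }, numeric(length(classes))))
  attr(out, "scores") <- score_mat
  out
}

#' Mean expression of marker genes per assigned type
#'
#' The computation behind an identity-verification heatmap: mean normalized
#' expression of each gene over the cells of each assigned type.
#'
#' @param nm a [normalized_matrix()].
#' @param cell_types per-cell type labels (named by cell id or in matrix
#'   column order).
#' @param genes genes to summarize.
#' @return gene x type matrix of mean expression.
#' @export
type_mean_expression <- function(nm, cell_types, genes = nm$gene_ids) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (!is.null(names(cell_types))) cell_types <- cell_types[nm$cell_ids]
  types <- sort(unique(cell_types))
  vapply(types, function(ty)
    Matrix::rowMeans(nm$values[genes, cell_types == ty, drop = FALSE]),
    numeric(length(genes)))
}
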