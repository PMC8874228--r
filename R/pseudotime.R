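#' Build a centroid-MST trajectory
#'
#' A minimal principal-graph surrogate: trajectory nodes are the cluster
#' centroids in PC space and edges form the Euclidean minimum spanning tree
#' over them (Kruskal's algorithm; equal edge weights broken by node-id
#' pair order, so the tree is deterministic). The root is the cluster named
#' by `root_cluster` — in the study design, the neuroblast-like cluster of
#' the early wild-type condition.
#'
#' @param e an `embedding` (for pseudotime, typically 150 components after
#'   batch correction).
#' @param labels a `cluster_labels` or a plain per-cell label vector
#'   (named by cell id or in embedding row order).
#' @param root_cluster label of the root cluster.
#' @return object of class `trajectory_graph`: `nodes` (centroid matrix,
#'   rownames = cluster labels), `edges` (from, to, weight), `root`,
#'   `node_dist` (geodesic node-to-node distances along the tree).
#' @export
build_trajectory <- function(e, labels, root_cluster) {
  stopifnot(inherits(e, "embedding"))
  lab <- if (inherits(labels, "cluster_labels")) labels$cluster else labels
  if (!is.null(names(lab))) lab <- lab[rownames(e$coordinates)]
  ids <- sort(unique(lab))
  root_cluster <- as.character(root_cluster)
  if (!root_cluster %in% as.character(ids))
    stop("root cluster '", root_cluster, "' not present")
  cent <- t(vapply(ids, function(cid)
    colMeans(e$coordinates[lab == cid, , drop = FALSE]),
    numeric(ncol(e$coordinates))))
  rownames(cent) <- as.character(ids)
  k <- nrow(cent)
  if (k == 1) {
    warning("single cluster: degenerate single-node tree, all pseudotime 0")
    return(structure(list(nodes = cent,
                          edges = data.frame(from = character(),
                                             to = character(),
                                             weight = numeric()),
                          root = root_cluster,
                          node_dist = matrix(0, 1, 1,
                            dimnames = list(rownames(cent), rownames(cent)))),
                     class = "trajectory_graph"))
  }
  # Kruskal MST with deterministic tie-break on (weight, i, j)
  pairs <- which(upper.tri(matrix(TRUE, k, k)), arr.ind = TRUE)
  w <- sqrt(rowSums((cent[pairs[, 1], , drop = FALSE] -
                     cent[pairs[, 2], , drop = FALSE])^2))
  ord <- order(w, pairs[, 1], pairs[, 2])
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- list()
  for (s in ord) {
    a <- find(pairs[s, 1]); b <- find(pairs[s, 2])
    if (a != b) {
      parent[a] <- b
      edges[[length(edges) + 1L]] <- c(pairs[s, 1], pairs[s, 2], w[s])
      if (length(edges) == k - 1L) break
    }
  }
  em <- do.call(rbind, edges)
  edges_df <- data.frame(from = rownames(cent)[em[, 1]],
                         to = rownames(cent)[em[, 2]],
                         weight = em[, 3], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges_df, directed = FALSE,
                                     vertices = rownames(cent))
  nd <- igraph::distances(g, weights = igraph::E(g)$weight)
  nd <- nd[rownames(cent), rownames(cent)]
  structure(list(nodes = cent, edges = edges_df, root = root_cluster,
                 node_dist = nd),
            class = "trajectory_graph")
}

#' @export
print.trajectory_graph <- function(x, ...) {
  cat(sprintf("trajectory_graph: %d nodes, %d edges, root '%s'\n",
              nrow(x$nodes), nrow(x$edges), x$root))
  invisible(x)
}

#' Pseudotime of cells along a trajectory
#'
#' Each cell is projected orthogonally onto its nearest tree edge (clamped
#' to the segment); its pseudotime is the geodesic arc length along the
#' tree from the root node to the projection point.
#'
#' @param traj a `trajectory_graph`.
#' @param coords cell x component matrix in the same PC space (or an
#'   `embedding`).
#' @return named numeric vector of pseudotime values (>= 0).
#' @export
compute_pseudotime <- function(traj, coords) {
  stopifnot(inherits(traj, "trajectory_graph"))
  if (inherits(coords, "embedding")) coords <- coords$coordinates
  if (any(!is.finite(coords))) stop("undefined cell coordinates")
  n <- nrow(coords)
  if (nrow(traj$edges) == 0) {
    return(stats::setNames(rep(0, n), rownames(coords)))
  }
  root_d <- traj$node_dist[traj$root, ]
  best_d2 <- rep(Inf, n)
  tau <- rep(0, n)
  for (ei in seq_len(nrow(traj$edges))) {
    u <- traj$edges$from[ei]; v <- traj$edges$to[ei]
    pu <- traj$nodes[u, ]; pv <- traj$nodes[v, ]
    len <- traj$edges$weight[ei]
    dir <- (pv - pu) / len
    rel <- sweep(coords, 2, pu, "-")
    s <- pmin(pmax(as.vector(rel %*% dir), 0), len)
    proj <- outer(s, dir) + matrix(pu, n, length(pu), byrow = TRUE)
    d2 <- rowSums((coords - proj)^2)
    t_here <- pmin(root_d[u] + s, root_d[v] + (len - s))
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    tau[upd] <- t_here[upd]
  }
  stats::setNames(tau, rownames(coords))
}

#' Fine-grained micro-clusters for trajectory building
#'
#' Partitions the embedding into many small k-means clusters so the
#' centroid-MST resolves gradients within cell types, analogous to the
#' dense node grid of a learned principal graph.
#'
#' @param e an `embedding`.
#' @param n_centers number of micro-clusters.
#' @param seed RNG seed for k-means initialization.
#' @return named integer vector of micro-cluster labels per cell.
#' @export
microcluster_labels <- function(e, n_centers = 40, seed = 0L) {
  stopifnot(inherits(e, "embedding"))
  set.seed(seed)
  km <- stats::kmeans(e$coordinates, centers = n_centers, iter.max = 50,
                      nstart = 5)
  stats::setNames(km$cluster, rownames(e$coordinates))
}

#' Choose the root cluster containing most of a reference cell set
#'
#' Implements "the NB in vitro cluster of WT35 as root": given the cells
#' known (or assigned) to be early-condition neuroblasts, returns the
#' cluster label holding the largest number of them.
#'
#' @param labels per-cell cluster labels (named by cell id).
#' @param root_cells cell ids defining the root population.
#' @return the root cluster label (character).
#' @export
root_cluster_for <- function(labels, root_cells) {
  lab <- if (inherits(labels, "cluster_labels")) labels$cluster else labels
  hits <- lab[intersect(names(lab), root_cells)]
  if (length(hits) == 0) stop("no root cells found among labeled cells")
  names(sort(table(hits), decreasing = TRUE))[1]
}

#' Pseudotime-dependent genes by quasi-Poisson GLM tests
#'
#' Per gene, fits a Poisson-family log-link GLM of raw counts on
#' `[1, tau, tau^2]` with `offset(log(total counts))` and compares it to
#' the intercept-only model. Because single-cell counts are overdispersed
#' relative to the Poisson, the deviance improvement is scaled by the
#' quasi-Poisson dispersion (mean squared Pearson residual of the full
#' fit, floored at 1) and referred to an F distribution on `(2, n - 3)` degrees of
#' freedom; on truly Poisson data the dispersion is ~1 and the test reduces
#' to the likelihood-ratio chi-squared. q-values are Benjamini-Hochberg.
#' The quadratic design is the minimal curvature-capable model of
#' expression change along a trajectory.
#'
#' @param cm a [count_matrix()] (raw counts) or gene x cell matrix.
#' @param tau per-cell pseudotime, aligned with the columns.
#' @return data.frame (gene, deviance, dispersion, p, q) for genes with
#'   any counts; all-zero genes are skipped. `deviance` is the unscaled
#'   deviance improvement of the quadratic fit.
#' @export
pseudotime_dependent_genes <- function(cm, tau) {
  counts <- if (inherits(cm, "count_matrix")) cm$values else cm
  if (length(tau) != ncol(counts)) stop("tau must align with cells")
  tot <- Matrix::colSums(counts)
  keep_cells <- tot > 0
  counts <- counts[, keep_cells, drop = FALSE]
  tau <- tau[keep_cells]
  off <- log(Matrix::colSums(counts))
  tau2 <- tau^2
  n <- length(tau)
  genes <- rownames(counts)[Matrix::rowSums(counts) > 0]
  rows <- lapply(genes, function(g) {
    y <- as.numeric(counts[g, ])
    fit1 <- stats::glm(y ~ tau + tau2 + offset(off), family = stats::poisson())
    fit0 <- stats::glm(y ~ 1 + offset(off), family = stats::poisson())
    dev <- max(fit0$deviance - fit1$deviance, 0)
    # dispersion floored at 1: counts are never underdispersed relative to
    # Poisson in a way the test should exploit
    disp <- max(sum(stats::residuals(fit1, type = "pearson")^2) /
                  stats::df.residual(fit1), 1)
    fstat <- (dev / 2) / disp
    data.frame(gene = g, deviance = dev, dispersion = disp,
               p = stats::pf(fstat, 2, n - 3, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' One-sided pseudotime contrast between conditions
#'
#' One-sided Wilcoxon rank-sum comparing the pseudotime distributions of
#' two strata (e.g. mutant vs wild-type mature dopaminergic neurons at the
#' late timepoint), reporting the tested direction and p.
#'
#' @param tau1,tau2 pseudotime samples for the two strata.
#' @param alternative `"greater"` tests whether `tau1` is stochastically
#'   larger than `tau2`; `"less"` the reverse.
#' @return list with `p`, `alternative`, `median1`, `median2`, `n1`, `n2`.
#' @export
contrast_pseudotime <- function(tau1, tau2,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(tau1) == 0 || length(tau2) == 0) {
    warning("empty stratum; contrast skipped")
    return(NULL)
  }
  wt <- suppressWarnings(stats::wilcox.test(tau1, tau2,
                                            alternative = alternative))
  list(p = wt$p.value, alternative = alternative,
       median1 = stats::median(tau1), median2 = stats::median(tau2),
       n1 = length(tau1), n2 = length(tau2))
}
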