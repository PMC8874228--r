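#' Select highly variable genes
#'
#' Ranks genes by standardized variance: the per-gene variance of the
#' log-normalized values divided by a mean-variance trend fitted across
#' genes (running median of variance over mean-ranked genes, with a wide
#' window so blocks of genuinely hypervariable genes cannot inflate their
#' own trend). Ties are broken deterministically by gene name.
#'
#' @param nm a [normalized_matrix()].
#' @param n number of genes to return (`n <=` number of genes).
#' @return character vector of `n` gene names, ranking order.
#' @export
select_hvg <- function(nm, n = 2000) {
  stopifnot(inherits(nm, "normalized_matrix"))
  v <- nm$values
  if (n > nrow(v)) stop("n exceeds the number of genes")
  nc <- ncol(v)
  mu <- Matrix::rowMeans(v)
  ex2 <- Matrix::rowSums(v^2) / nc
  va <- (ex2 - mu^2) * nc / (nc - 1)
  va[va < 1e-12] <- 0
  if (all(va <= 0)) stop("no variable genes: the matrix is constant")
  ord_mu <- order(mu)
  k <- min(max(101, nrow(v) %/% 10), nrow(v))
  if (k %% 2 == 0) k <- k - 1
  trend_sorted <- stats::runmed(va[ord_mu], k, endrule = "median")
  trend <- numeric(length(va))
  trend[ord_mu] <- pmax(trend_sorted, 1e-12)
  std_var <- va / trend
  std_var[va <= 0] <- -Inf  # a zero-variance gene is never selected
  ord <- order(-std_var, nm$gene_ids)
  nm$gene_ids[ord][seq_len(n)]
}

#' Scale selected genes and compute principal components
#'
#' Per-gene centering to mean 0 and scaling to unit variance, with
#' standardized values clipped at +/-10, followed by PCA on the gene-gene
#' covariance of the selected genes. The decomposition is exact (dense
#' eigendecomposition) for up to 2,000 genes; above that an implicitly
#' restarted Lanczos solver (irlba) is used under the given seed.
#'
#' @param nm a [normalized_matrix()].
#' @param genes ordered gene subset to use (e.g. from [select_hvg()]).
#' @param n_pcs number of components to return.
#' @param seed RNG seed for the randomized solver path.
#' @param clip absolute clip bound for standardized values.
#' @return object of class `embedding`: list with `coordinates`
#'   (cell x component), `component_variances` (nonincreasing),
#'   `genes_used`, `corrected` flag, `cell_ids`.
#' @export
scale_and_pca <- function(nm, genes, n_pcs = 20, seed = 0L, clip = 10) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (!all(genes %in% nm$gene_ids)) stop("unknown genes requested")
  x <- t(.dense_values(nm, genes = genes))     # cells x genes
  n <- nrow(x); p <- ncol(x)
  ctr <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1                            # constant gene scales to 0
  x <- sweep(sweep(x, 2, ctr, "-"), 2, sdv, "/")
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  max_rank <- min(n - 1L, p)
  if (n_pcs > max_rank) {
    warning("n_pcs exceeds the matrix rank; truncating to ", max_rank)
    n_pcs <- max_rank
  }
  # re-center after clipping so components are exact covariance eigenvectors
  x <- sweep(x, 2, colMeans(x), "-")
  if (p <= 2000) {
    cv <- crossprod(x) / (n - 1)
    eg <- eigen(cv, symmetric = TRUE)
    rot <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
    lam <- pmax(eg$values[seq_len(n_pcs)], 0)
  } else {
    set.seed(seed)
    sv <- irlba::irlba(x, nv = n_pcs)
    rot <- sv$v
    lam <- sv$d^2 / (n - 1)
  }
  # deterministic sign convention: largest-magnitude loading positive
  sgn <- apply(rot, 2, function(u) sign(u[which.max(abs(u))]))
  rot <- sweep(rot, 2, sgn, "*")
  coords <- x %*% rot
  rownames(coords) <- nm$cell_ids
  colnames(coords) <- paste0("PC", seq_len(n_pcs))
  structure(list(coordinates = coords, component_variances = lam,
                 genes_used = genes, corrected = FALSE,
                 cell_ids = nm$cell_ids),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d cells x %d components%s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              if (isTRUE(x$corrected)) " (batch-corrected)" else ""))
  invisible(x)
}

#' Mutual-nearest-neighbor batch correction in PC space
#'
#' Removes dataset-to-dataset shifts in a joint PCA embedding. The first
#' batch (in order of appearance) is the reference; each further batch is
#' corrected against the pool of already-corrected cells. Mutual nearest
#' neighbor pairs across the batch boundary define pair-wise correction
#' vectors (reference minus query); each query cell is moved by a
#' Gaussian-kernel weighted average of these vectors, with bandwidth `sigma`
#' (default: the median pair distance). Shared populations are mixed;
#' batch-unique populations, having no mutual neighbors nearby, move with
#' their nearest shared population and remain separated.
#'
#' Because MNN pairs concentrate where the batches face each other, a single
#' pass underestimates large batch separations; the matching and correction
#' are therefore iterated until the applied shifts become negligible (or
#' `max_iter` is reached), which converges for shift-dominated batch
#' effects while the Gaussian kernel keeps genuinely local differences
#' local.
#'
#' @param e an `embedding` (joint PCA over all batches).
#' @param batch per-cell batch labels (length = number of cells).
#' @param k neighbors used on each side of the MNN search.
#' @param sigma Gaussian smoothing bandwidth in PC-space distance units;
#'   `NULL` for 3x the median MNN pair distance (a wide kernel that favors
#'   translation-like corrections and so preserves within-batch geometry).
#' @param max_iter maximum matching/correction passes per batch.
#' @param tol stop when the median applied shift drops below `tol` times
#'   the initial median pair distance.
#' @return corrected `embedding` (`corrected = TRUE`). With a single batch,
#'   the input is returned unchanged. If no MNN pairs are found for a batch
#'   a warning is raised and that batch is left uncorrected (flagged in
#'   `provenance`).
#' @export
mnn_correct <- function(e, batch, k = 20, sigma = NULL, max_iter = 8,
                        tol = 0.05) {
  stopifnot(inherits(e, "embedding"))
  batch <- as.character(batch)
  if (length(batch) != nrow(e$coordinates))
    stop("batch labels must cover every cell")
  levels <- unique(batch)
  if (length(levels) < 2) return(e)
  coords <- e$coordinates
  ref_idx <- which(batch == levels[1])
  uncorrected <- character()
  for (b in levels[-1]) {
    q_idx <- which(batch == b)
    scale0 <- NULL
    for (it in seq_len(max_iter)) {
      pairs <- .mnn_pairs(coords, ref_idx, q_idx, k)
      if (is.null(pairs)) {
        if (it == 1) {
          warning("no MNN pairs found for batch '", b, "'; left uncorrected")
          uncorrected <- c(uncorrected, b)
        }
        break
      }
      vecs <- coords[ref_idx[pairs$r], , drop = FALSE] -
        coords[q_idx[pairs$q], , drop = FALSE]
      anchors <- coords[q_idx[pairs$q], , drop = FALSE]
      pd <- sqrt(rowSums(vecs^2))
      if (is.null(scale0)) scale0 <- max(stats::median(pd), 1e-8)
      sg <- if (is.null(sigma)) 3 * max(stats::median(pd), 1e-8) else sigma
      # Gaussian weights with global support over (a subsample of) the pairs,
      # so the smoothed field degrades gracefully to a translation and keeps
      # within-batch geometry intact
      if (length(pairs$q) > 2000) {
        sub <- unique(round(seq(1, length(pairs$q), length.out = 2000)))
        anchors <- anchors[sub, , drop = FALSE]
        vecs <- vecs[sub, , drop = FALSE]
      }
      qc <- coords[q_idx, , drop = FALSE]
      d2 <- outer(rowSums(qc^2), rowSums(anchors^2), "+") -
        2 * tcrossprod(qc, anchors)
      w <- exp(-pmax(d2, 0) / (2 * sg^2))
      w <- w / pmax(rowSums(w), 1e-12)
      shift <- w %*% vecs
      coords[q_idx, ] <- qc + shift
      if (stats::median(sqrt(rowSums(shift^2))) < tol * scale0) break
    }
    ref_idx <- c(ref_idx, q_idx)
  }
  e$coordinates <- coords
  e$corrected <- TRUE
  e$provenance <- list(uncorrected_batches = uncorrected)
  e
}

# internal: mutual nearest-neighbor pairs between reference and query cells
.mnn_pairs <- function(coords, ref_idx, q_idx, k) {
  kk <- min(k, length(ref_idx), length(q_idx))
  nn_rq <- RANN::nn2(coords[ref_idx, , drop = FALSE],
                     coords[q_idx, , drop = FALSE], k = kk)
  nn_qr <- RANN::nn2(coords[q_idx, , drop = FALSE],
                     coords[ref_idx, , drop = FALSE], k = kk)
  pair_q <- rep(seq_along(q_idx), kk)
  pair_r <- as.vector(nn_rq$nn.idx)
  mutual <- vapply(seq_along(pair_q), function(s) {
    pair_q[s] %in% nn_qr$nn.idx[pair_r[s], ]
  }, logical(1))
  if (!any(mutual)) return(NULL)
  list(q = pair_q[mutual], r = pair_r[mutual])
}

#' Shared-nearest-neighbor graph
#'
#' Builds the undirected cell graph used for Louvain clustering: each cell
#' is connected to every cell sharing part of its k-neighborhood, with edge
#' weight the Jaccard overlap of the two k-neighborhoods (self excluded).
#' Zero-weight edges are dropped.
#'
#' @param e an `embedding`.
#' @param k neighborhood size (`k >= 2`, `k <` number of cells).
#' @return an [igraph::graph] with vertex names = cell ids and edge
#'   attribute `weight`.
#' @export
knn_graph <- function(e, k = 20) {
  stopifnot(inherits(e, "embedding"))
  n <- nrow(e$coordinates)
  if (k <= 1) stop("k must be at least 2")
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- RANN::nn2(e$coordinates, k = k + 1)
  idx <- nn$nn.idx
  # drop self (usually column 1; guard against exact duplicates)
  nb <- t(vapply(seq_len(n), function(i) {
    row <- idx[i, ]
    row <- row[row != i]
    if (length(row) < k) row <- c(row, idx[i, 1][idx[i, 1] == i])[seq_len(k)]
    row[seq_len(k)]
  }, integer(k)))
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nb),
                            x = 1, dims = c(n, n))
  s <- Matrix::tcrossprod(a)              # |N_i intersect N_j|
  s <- methods::as(methods::as(s, "CsparseMatrix"), "generalMatrix")
  tr <- Matrix::which(s != 0, arr.ind = TRUE)
  tr <- tr[tr[, 1] < tr[, 2], , drop = FALSE]
  inter <- s[tr]
  jac <- inter / (2 * k - inter)
  keep <- jac > 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr[keep, 1], to = tr[keep, 2], weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  igraph::V(g)$name <- e$cell_ids
  g
}
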