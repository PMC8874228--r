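# shared fixture builders for the test suite; everything is generated in
# code at test time

# minimal two-type configuration where WT and MUT differ only through the
# injected genotype-responsive genes
two_group_config <- function(seed, n_genes = 2200, n_de_genes = 100,
                             n_cells = 200) {
  types <- c("A", "B")
  tp <- rbind(WT35 = c(0.5, 0.5), MUT35 = c(0.5, 0.5))
  colnames(tp) <- types
  sim_config(n_genes = n_genes, n_cells_per_condition = n_cells,
             cell_types = types, type_proportions = tp,
             atlas_proportions = stats::setNames(c(0.5, 0.5), types),
             type_time_offset = stats::setNames(c(0, 0), types),
             condition_time = c(WT35 = 9, MUT35 = 9),
             mutant_shift = 0, mutant_arrest = Inf,
             n_markers_per_type = 10, n_time_genes = 0,
             n_de_genes = n_de_genes, de_log2fc = 1,
             doublet_rate = 0, seed = seed)
}

# k equally frequent types in one condition, marker-driven structure only
flat_type_config <- function(seed, types = c("A", "B", "C"),
                             n_genes = 1000, n_cells = 900,
                             marker_fold = 4, n_markers_per_type = 20,
                             n_time_genes = 50) {
  k <- length(types)
  tp <- matrix(rep(1 / k, k), 1, dimnames = list("COND", types))
  sim_config(n_genes = n_genes, n_cells_per_condition = n_cells,
             cell_types = types, type_proportions = tp,
             atlas_proportions = stats::setNames(rep(1 / k, k), types),
             type_time_offset = stats::setNames(rep(0, k), types),
             condition_time = c(COND = 9), marker_fold = marker_fold,
             n_markers_per_type = n_markers_per_type,
             n_time_genes = n_time_genes, n_de_genes = 0,
             doublet_rate = 0, seed = seed)
}

# small staging configuration (atlas + organoid conditions, no genotype
# effect) sized for repeated simulation
staging_config <- function(seed, n_genes = 800, cells_per_week = 2000) {
  sim_config(n_genes = n_genes, n_cells_per_week = cells_per_week,
             n_cells_per_condition = cells_per_week,
             n_markers_per_type = 10, n_time_genes = 100, n_de_genes = 0,
             seed = seed)
}

# count_matrix with prescribed per-cell feature counts and MT fractions
qc_fixture <- function(n_features, mt_target, n_genes = 3000) {
  stopifnot(length(n_features) == length(mt_target))
  n <- length(n_features)
  genes <- c(sprintf("G%04d", seq_len(n_genes - 10)),
             sprintf("MT-%02d", 1:10))
  mt_idx <- n_genes - 10 + 1
  ii <- jj <- xx <- integer(0)
  for (c in seq_len(n)) {
    f <- n_features[c]
    # f - 1 singleton non-MT genes plus one MT gene carrying the MT mass
    nonmt <- seq_len(f - 1)
    mtc <- max(1, round(mt_target[c] * (f - 1) / (1 - mt_target[c])))
    ii <- c(ii, nonmt, mt_idx)
    jj <- c(jj, rep(c, f))
    xx <- c(xx, rep(1, f - 1), mtc)
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_genes, n))
  rownames(m) <- genes
  colnames(m) <- sprintf("cell%02d", seq_len(n))
  count_matrix(m)
}

# random sparse nonnegative-integer count matrix
random_counts <- function(n_genes, n_cells, seed, lambda = 0.5,
                          n_mt = 10) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  m[1, ] <- m[1, ] + 1   # no zero-total cells
  rownames(m) <- c(sprintf("MT-%02d", seq_len(n_mt)),
                   sprintf("G%04d", seq_len(n_genes - n_mt)))
  colnames(m) <- sprintf("c%04d", seq_len(n_cells))
  count_matrix(m)
}

# embedding object from a plain coordinate matrix
as_embedding <- function(coords) {
  if (is.null(rownames(coords)))
    rownames(coords) <- sprintf("cell%04d", seq_len(nrow(coords)))
  structure(list(coordinates = coords,
                 component_variances = rep(1, ncol(coords)),
                 genes_used = character(), corrected = FALSE,
                 cell_ids = rownames(coords)),
            class = "embedding")
}

# brute-force minimum spanning tree weight by enumerating all spanning trees
enumerate_mst_weight <- function(centroids) {
  k <- nrow(centroids)
  d <- as.matrix(stats::dist(centroids))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (sel in utils::combn(nrow(pairs), k - 1, simplify = FALSE)) {
    g <- igraph::graph_from_edgelist(cbind(pairs[sel, 1], pairs[sel, 2]),
                                     directed = FALSE)
    if (igraph::vcount(g) < k) next
    if (igraph::is_connected(g) && igraph::ecount(g) == k - 1)
      best <- min(best, sum(d[pairs[sel, , drop = FALSE]]))
  }
  best
}

# per-cell truth vector aligned to a normalized matrix
truth_vector <- function(sims, nm, field = "true_type") {
  v <- do.call(c, unname(lapply(sims, function(s)
    stats::setNames(s$truth[[field]], s$counts$cell_ids))))
  v[nm$cell_ids]
}

# simulate all four organoid conditions for a config
simulate_conditions <- function(cfg) {
  conds <- rownames(cfg$type_proportions)
  sims <- lapply(conds, function(cc) simulate_dataset(cfg, cc))
  names(sims) <- conds
  sims
}
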