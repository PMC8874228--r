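#' Merge count matrices that share a gene universe
#'
#' Column-binds several datasets (e.g. the four organoid conditions after
#' QC) into one [count_matrix()], carrying the shared metadata columns.
#'
#' @param lst list of `count_matrix` objects with identical `gene_ids`.
#' @return a merged `count_matrix`.
#' @export
merge_counts <- function(lst) {
  stopifnot(length(lst) >= 1)
  g <- lst[[1]]$gene_ids
  for (m in lst) if (!identical(m$gene_ids, g))
    stop("datasets do not share a gene universe")
  vals <- do.call(cbind, lapply(lst, `[[`, "values"))
  keep <- Reduce(intersect, lapply(lst, function(m)
    setdiff(colnames(m$cell_meta),
            c("barcode", "n_features", "total_counts", "mt_fraction"))))
  meta <- do.call(rbind, lapply(lst, function(m)
    m$cell_meta[, keep, drop = FALSE]))
  count_matrix(vals, cell_meta = meta)
}

#' QC, mitochondrial-gene removal and normalization for a set of conditions
#'
#' The standard pre-processing chain applied per dataset — cell filtering,
#' MT-gene removal, merge, log-normalization — returning one normalized
#' matrix over all conditions.
#'
#' @param counts_list list of raw `count_matrix` objects (one per condition).
#' @param thresholds a [qc_thresholds()].
#' @return a [normalized_matrix()] over the merged, QC-passed cells.
#' @export
qc_normalize <- function(counts_list, thresholds = qc_thresholds()) {
  qcd <- lapply(counts_list, function(m)
    drop_mt_genes(filter_cells(m, thresholds)))
  lognormalize(merge_counts(qcd), thresholds)
}

#' Trajectory study configuration: the neuronal differentiation lineage
#'
#' The simulation bench for pseudotemporal genotype contrasts: the dominant
#' neuronal lineage (NB in vitro -> progenitor -> yNEUR -> mDN) as a
#' developmental ladder (per-type latent-time offsets spanning ~1.8 weeks),
#' equal composition across the four organoid conditions, moderate marker
#' contrast, and the default mutant acceleration + arrest. Side lineages
#' (glia, vasculature) are omitted: a centroid-MST represents a single
#' differentiation continuum faithfully, while populations lying at similar
#' latent times on separate expression branches can attach to the tree at
#' arbitrary ends (a known limitation of the minimal trajectory model).
#'
#' @param seed master seed.
#' @param n_cells_per_condition cells per condition.
#' @param n_de_genes genotype-responsive genes (present by default: the
#'   mutant expression axis is part of the phenotype).
#' @return a [sim_config()].
#' @export
trajectory_bench_config <- function(seed, n_cells_per_condition = 1200,
                                    n_de_genes = 60) {
  types <- c("NB_invitro", "progenitor", "yNEUR", "mDN")
  prop <- c(0.40, 0.15, 0.25, 0.20)
  tp <- rbind(WT35 = prop, WT70 = prop, MUT35 = prop, MUT70 = prop)
  colnames(tp) <- types
  sim_config(n_genes = 1000, n_cells_per_condition = n_cells_per_condition,
             cell_types = types, type_proportions = tp,
             atlas_proportions = stats::setNames(rep(1 / 4, 4), types),
             type_time_offset = stats::setNames(c(-1.2, -0.6, 0, 0.6), types),
             marker_fold = 2, n_markers_per_type = 12, n_time_genes = 120,
             n_de_genes = n_de_genes, seed = seed)
}

#' Lineage-ladder configuration for pseudotime recovery
#'
#' A single condition whose four lineage stages span ~3 latent weeks, used
#' to measure how well trajectory pseudotime recovers true latent time
#' along a differentiation continuum.
#'
#' @param seed master seed.
#' @param n_cells cells in the single condition.
#' @return a [sim_config()].
#' @export
lineage_ladder_config <- function(seed, n_cells = 2000) {
  types <- c("NB_invitro", "progenitor", "yNEUR", "mDN")
  tp <- rbind(WT35 = c(0.3, 0.2, 0.25, 0.25))
  colnames(tp) <- types
  sim_config(n_genes = 1000, n_cells_per_condition = n_cells,
             cell_types = types, type_proportions = tp,
             atlas_proportions = stats::setNames(rep(1 / 4, 4), types),
             type_time_offset = stats::setNames(c(-1.5, -0.5, 0.5, 1.5), types),
             marker_fold = 2, condition_time = c(WT35 = 9),
             n_markers_per_type = 12, n_time_genes = 120,
             n_de_genes = 0, seed = seed)
}

#' Reference trajectory with projection of all cells
#'
#' Builds the developmental reference tree from a subset of cells (for the
#' genotype contrast: the wild-type cells, whose differentiation path is the
#' reference), micro-clustering them and rooting the centroid-MST at the
#' cluster holding most of `root_cells`; every cell in the embedding — also
#' those outside the reference — is then projected onto the tree for its
#' pseudotime. Building the tree from the reference only keeps expression
#' axes unique to the query population (e.g. a mutant expression program)
#' from distorting the tree, while projection still places query cells by
#' their position along the shared developmental axis.
#'
#' @param e an `embedding` over all cells.
#' @param reference_cells cell ids used to build the tree.
#' @param root_cells cell ids defining the root population (e.g. early
#'   wild-type neuroblasts).
#' @param n_nodes number of micro-cluster nodes.
#' @param seed RNG seed for micro-clustering.
#' @return list with `trajectory` (a `trajectory_graph`), `tau` (named
#'   pseudotime for every cell in `e`), `labels` (micro-cluster labels of
#'   the reference cells), `root`.
#' @export
reference_trajectory <- function(e, reference_cells, root_cells,
                                 n_nodes = 20, seed = 0L) {
  stopifnot(inherits(e, "embedding"))
  ref <- e
  keep <- e$cell_ids %in% reference_cells
  ref$coordinates <- e$coordinates[keep, , drop = FALSE]
  ref$cell_ids <- e$cell_ids[keep]
  labels <- microcluster_labels(ref, n_nodes, seed = seed)
  root <- root_cluster_for(labels, root_cells)
  traj <- build_trajectory(ref, labels, root)
  tau <- compute_pseudotime(traj, e)
  list(trajectory = traj, tau = tau, labels = labels, root = root)
}
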