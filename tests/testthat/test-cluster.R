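test_that("Louvain recovers obvious community structure", {
  # two disconnected 4-cliques -> exactly the two cliques
  edges <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- paste0("c", 1:8)
  cl <- louvain_cluster(g, resolution = 0.5, seed = 1)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[1:4])), 1)
  expect_equal(length(unique(cl$cluster[5:8])), 1)
  expect_true(min(cl$cluster) == 0)
  # modularity beats the trivial all-in-one partition (which scores 0)
  expect_gt(cl$modularity, 0)

  # vanishing resolution collapses a connected graph to one community
  gc <- igraph::add_edges(g, c(4, 5))
  igraph::E(gc)$weight <- 1
  cl0 <- louvain_cluster(gc, resolution = 0.01, seed = 1)
  expect_equal(length(unique(cl0$cluster)), 1)

  expect_error(louvain_cluster(igraph::make_empty_graph(0)), "empty")
  expect_error(louvain_cluster(g, resolution = 0), "resolution")
})

test_that("Louvain clustering recovers simulated cell types", {
  cfg <- flat_type_config(13, types = c("A", "B", "C"), n_cells = 900)
  sim <- simulate_dataset(cfg, "COND")
  nm <- lognormalize(drop_mt_genes(filter_cells(sim$counts)))
  emb <- scale_and_pca(nm, select_hvg(nm, 200), n_pcs = 20)
  cl <- louvain_cluster(knn_graph(emb, 20), resolution = 0.5, seed = 13)
  truth <- truth_vector(list(sim), nm)
  expect_gte(mclust::adjustedRandIndex(cl$cluster, truth), 0.9)
  # determinism under a fixed seed
  cl2 <- louvain_cluster(knn_graph(emb, 20), resolution = 0.5, seed = 13)
  expect_identical(cl$cluster, cl2$cluster)
})

test_that("over-split clusters merge by centroid proximity and marker overlap", {
  # engineered 4-cluster embedding with one near-duplicate pair
  set.seed(7)
  centers <- rbind(c(0, 0), c(0.05, 0), c(10, 0), c(0, 10))
  coords <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(60, sd = 0.01), 30, 2), 2, centers[i, ], "+")))
  e <- as_embedding(coords)
  lab <- structure(list(cluster = stats::setNames(rep(0:3, each = 30),
                                                  rownames(coords)),
                        resolution = 0.5, modularity = 0.5, seed = 1),
                   class = "cluster_labels")
  mk <- list("0" = paste0("g", 1:100), "1" = paste0("g", 1:100),
             "2" = paste0("h", 1:100), "3" = paste0("k", 1:100))
  merged <- merge_overclustered(lab, e, mk,
                                centroid_quantile = 0.1, jaccard_min = 0.5)
  expect_equal(length(unique(merged$cluster)), 3)
  expect_equal(merged$cluster[1], merged$cluster[31])   # the pair merged
  expect_false(merged$cluster[61] == merged$cluster[91])

  # identical marker lists but jaccard_min = 1 with distinct lists: identity
  mk_dist <- list("0" = paste0("g", 1:100), "1" = paste0("x", 1:100),
                  "2" = paste0("h", 1:100), "3" = paste0("k", 1:100))
  same <- merge_overclustered(lab, e, mk_dist,
                              centroid_quantile = 0.1, jaccard_min = 1.0)
  expect_equal(length(unique(same$cluster)), 4)

  # never increases the cluster count; idempotent on the merged result
  again <- merge_overclustered(merged, e, mk[c("0", "2", "3")],
                               centroid_quantile = 0.1, jaccard_min = 0.5)
  expect_lte(length(unique(again$cluster)), length(unique(merged$cluster)))
})

test_that("marker ranking surfaces cluster-exclusive genes first", {
  x <- matrix(0.1, 5, 30)
  x[1, 1:10] <- 5                    # gene 1 exclusive to cluster 0
  rownames(x) <- paste0("G", 1:5)
  colnames(x) <- paste0("c", 1:30)
  nm <- normalized_matrix(
    methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                            "CsparseMatrix"), "generalMatrix"),
    data.frame(barcode = colnames(x), row.names = colnames(x)),
    provenance = list(scale_factor = 1e4, log_base = "e"))
  lab <- structure(list(cluster = stats::setNames(rep(c(0, 1, 2), each = 10),
                                                  colnames(x)),
                        resolution = 0.5, modularity = 0, seed = 1),
                   class = "cluster_labels")
  mk <- rank_cluster_markers(nm, lab, top_n = 5)
  expect_equal(mk[["0"]][1], "G1")

  # identical expression across clusters: nothing is up-regulated
  x2 <- matrix(rep(c(3, 1, 2, 0.5, 1.5), 30), 5, 30,
               dimnames = dimnames(x))
  nm2 <- normalized_matrix(
    methods::as(methods::as(Matrix::Matrix(x2, sparse = TRUE),
                            "CsparseMatrix"), "generalMatrix"),
    data.frame(barcode = colnames(x2), row.names = colnames(x2)),
    provenance = list(scale_factor = 1e4, log_base = "e"))
  mk2 <- rank_cluster_markers(nm2, lab, top_n = 5)
  expect_true(all(lengths(mk2) == 0))
})

test_that("simulated marker programs are recovered in the cluster top lists", {
  cfg <- flat_type_config(17, types = c("A", "B", "C"), n_cells = 600,
                          n_markers_per_type = 20)
  sim <- simulate_dataset(cfg, "COND")
  nm <- lognormalize(drop_mt_genes(filter_cells(sim$counts)))
  truth <- truth_vector(list(sim), nm)
  lab <- structure(list(cluster = stats::setNames(
    match(truth, c("A", "B", "C")) - 1L, nm$cell_ids),
    resolution = 0.5, modularity = 0, seed = 1), class = "cluster_labels")
  mk <- rank_cluster_markers(nm, lab, top_n = 20)
  mm <- sim$truth$marker_matrix_truth
  for (i in 1:3) {
    ty <- c("A", "B", "C")[i]
    program <- rownames(mm)[mm[, ty] == 1]
    expect_gte(length(intersect(mk[[as.character(i - 1)]], program)), 18)
  }
})

test_that("type assignment scores marker overlap with tie and unknown rules", {
  mm_mat <- matrix(0, 6, 3,
                   dimnames = list(paste0("g", 1:6), c("DN", "glia", "NB")))
  mm_mat[1:2, "DN"] <- 1
  mm_mat[3:4, "glia"] <- 1
  mm_mat[5:6, "NB"] <- 1
  mm <- marker_matrix(mm_mat)

  # exact match
  a <- assign_types(list("0" = c("g1", "g2")), mm)
  expect_equal(a$type, "DN")
  expect_equal(a$score, 2)
  expect_false(a$ambiguous)

  # tie between DN and glia: lexicographically first, flagged
  t2 <- assign_types(list("0" = c("g1", "g3")), mm)
  expect_equal(t2$type, "DN")
  expect_true(t2$ambiguous)

  # no overlap at all: unknown
  u <- assign_types(list("0" = c("zz1", "zz2")), mm)
  expect_equal(u$type, "unknown")

  # invariant to marker-matrix column permutation
  mm_perm <- marker_matrix(mm_mat[, c(3, 1, 2)])
  expect_equal(assign_types(list("0" = c("g1", "g3")), mm_perm)$type, "DN")

  # subtype scores combine into generic classes (sum rule)
  mm_sub <- matrix(0, 4, 3,
                   dimnames = list(paste0("g", 1:4),
                                   c("DN0", "DN1", "glia")))
  mm_sub[1, "DN0"] <- 1; mm_sub[2, "DN1"] <- 1; mm_sub[3:4, "glia"] <- 1
  mm2 <- marker_matrix(mm_sub, class_map = c(DN0 = "DN", DN1 = "DN",
                                             glia = "glia"))
  s <- assign_types(list("0" = c("g1", "g2", "g3")), mm2)
  expect_equal(s$type, "DN")      # 1 + 1 beats 1
  expect_equal(s$score, 2)
  s_max <- assign_types(list("0" = c("g1", "g2", "g3")), mm2,
                        combine = "max")
  expect_equal(s_max$type, "DN")  # max(1,1) ties glia 1 -> lexicographic
  expect_true(s_max$ambiguous)
})

test_that("mean expression per assigned type summarizes marker activity", {
  cfg <- flat_type_config(19, types = c("A", "B"), n_genes = 300,
                          n_cells = 200, n_markers_per_type = 5)
  sim <- simulate_dataset(cfg, "COND")
  nm <- lognormalize(drop_mt_genes(sim$counts))
  truth <- truth_vector(list(sim), nm)
  mm <- sim$truth$marker_matrix_truth
  mkA <- rownames(mm)[mm[, "A"] == 1]
  hm <- type_mean_expression(nm, truth, genes = mkA)
  expect_true(all(hm[, "A"] > hm[, "B"]))
})
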