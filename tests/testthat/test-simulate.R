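test_that("simulated datasets have the requested size and metadata", {
  cfg <- sim_config(n_genes = 500, n_cells_per_condition = 500,
                    n_markers_per_type = 5, n_time_genes = 30,
                    n_de_genes = 20, seed = 1)
  sim <- simulate_dataset(cfg, "WT35")
  expect_s3_class(sim$counts, "count_matrix")
  expect_equal(ncol(sim$counts$values), 500)
  expect_equal(nrow(sim$counts$values), 500)
  expect_true(all(sim$counts$values@x >= 0))
  expect_true(all(sim$counts$values@x == round(sim$counts$values@x)))
  expect_setequal(unique(sim$counts$cell_meta$condition), "WT35")
  expect_setequal(unique(sim$counts$cell_meta$genotype), "WT")
  expect_length(sim$truth$true_type, 500)
  expect_true(all(sim$truth$true_type %in% cfg$cell_types))
})

test_that("identical configs give bit-identical data", {
  cfg <- sim_config(n_genes = 300, n_cells_per_condition = 150,
                    n_cells_per_week = 100, n_markers_per_type = 5,
                    n_time_genes = 20, n_de_genes = 10, seed = 42)
  a <- simulate_dataset(cfg, "MUT70")
  b <- simulate_dataset(cfg, "MUT70")
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  at1 <- simulate_reference_atlas(cfg)
  at2 <- simulate_reference_atlas(cfg)
  expect_identical(serialize(at1, NULL), serialize(at2, NULL))
})

test_that("count marginals match the negative-binomial law", {
  # one type, no markers/time structure, fixed size factors: every gene is
  # a plain NB sample whose moments are recoverable
  types <- "A"
  tp <- matrix(1, 1, 1, dimnames = list("COND", types))
  cfg <- sim_config(n_genes = 80, n_cells_per_condition = 5000,
                    cell_types = types, type_proportions = tp,
                    atlas_proportions = stats::setNames(1, types),
                    type_time_offset = stats::setNames(0, types),
                    condition_time = c(COND = 9), marker_fold = 1,
                    n_markers_per_type = 5, n_time_genes = 0,
                    n_de_genes = 0, nb_dispersion = 0.5,
                    library_size_lognormal = c(0, 0), doublet_rate = 0,
                    latent_time_sd = 0, seed = 1)
  sim <- simulate_dataset(cfg, "COND")
  x <- as.matrix(sim$counts$values)
  non_mt <- !grepl("^MT-", rownames(x))
  x <- x[non_mt, ]
  mu_true <- sim$truth$.universe$base[non_mt]
  n <- ncol(x)
  m_hat <- rowMeans(x)
  v_hat <- apply(x, 1, stats::var)
  # mean within 3 standard errors for nearly all genes
  se <- sqrt(v_hat / n)
  frac_ok <- mean(abs(m_hat - mu_true) <= 3 * se)
  expect_gte(frac_ok, 0.95)
  # variance follows var = mu + phi mu^2
  v_pred <- mu_true + 0.5 * mu_true^2
  expect_lt(stats::median(abs(v_hat / v_pred - 1)), 0.15)
  # method-of-moments dispersion
  phi_hat <- (v_hat - m_hat) / m_hat^2
  expect_lt(abs(stats::median(phi_hat) - 0.5), 0.1)
})

test_that("marker contrast converges to marker_fold", {
  cfg <- flat_type_config(3, types = c("A", "B"), n_genes = 400,
                          n_cells = 4000, marker_fold = 4,
                          n_markers_per_type = 10, n_time_genes = 0)
  sim <- simulate_dataset(cfg, "COND")
  x <- as.matrix(sim$counts$values)
  truth <- sim$truth
  mkA <- rownames(truth$marker_matrix_truth)[truth$marker_matrix_truth[, "A"] == 1]
  inA <- truth$true_type == "A"
  ratio <- rowMeans(x[mkA, inA]) / rowMeans(x[mkA, !inA])
  expect_lt(abs(mean(ratio) - 4), 0.4)
})

test_that("doublet flags honor the configured rate", {
  cfg <- sim_config(n_genes = 300, n_cells_per_condition = 200,
                    n_markers_per_type = 5, n_time_genes = 20,
                    n_de_genes = 0, doublet_rate = 0, seed = 2)
  sim <- simulate_dataset(cfg, "WT35")
  expect_false(any(sim$truth$doublet_flags))
})

test_that("invalid configurations are rejected", {
  tp <- rbind(WT35 = c(0.6, 0.3))  # sums to 0.9
  colnames(tp) <- c("A", "B")
  expect_error(
    sim_config(cell_types = c("A", "B"), type_proportions = tp,
               atlas_proportions = stats::setNames(c(0.5, 0.5), c("A", "B")),
               type_time_offset = stats::setNames(c(0, 0), c("A", "B")),
               condition_time = c(WT35 = 9)),
    "sum to 1")
  expect_error(sim_config(n_genes = 0), "zero genes or cells")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(doublet_rate = 1.5), "doublet_rate")
  cfg <- sim_config(seed = 1)
  expect_error(simulate_dataset(cfg, "WT99"), "unknown condition")
})

test_that("reference atlas spans the configured weeks with monotone time genes", {
  cfg <- staging_config(7, n_genes = 500, cells_per_week = 2000)
  atlas <- simulate_reference_atlas(cfg)
  expect_named(atlas, paste0("w", 6:11))
  wk <- vapply(atlas, function(a) unique(a$counts$cell_meta$day_or_week),
               numeric(1))
  expect_equal(unname(wk), 6:11)
  # a positive-slope time gene increases strictly week over week
  uni <- atlas[[1]]$truth$.universe
  pos <- uni$gene_ids[uni$idx_time[uni$slopes > 0][1]]
  means <- vapply(atlas, function(a)
    mean(a$counts$values[pos, ]), numeric(1))
  expect_true(all(diff(means) > 0))
  cfg_bad <- cfg
  cfg_bad$weeks <- 6
  expect_error(simulate_reference_atlas(cfg_bad), "at least 2 weeks")
})

test_that("genotype effect shifts and caps latent time as configured", {
  # early acceleration and late arrest are visible in the generated truth
  cfg <- sim_config(n_genes = 400, n_cells_per_condition = 800,
                    n_markers_per_type = 5, n_time_genes = 30,
                    n_de_genes = 10, mutant_shift = 0.5,
                    mutant_arrest = 9.7,  # WT-late mean minus 0.3
                    seed = 11)
  t_mean <- function(cond)
    mean(simulate_dataset(cfg, cond)$truth$true_latent_time)
  expect_gt(t_mean("MUT35"), t_mean("WT35"))
  expect_lt(t_mean("MUT70"), t_mean("WT70"))

  # identity case: zero shift, infinite cap leaves the truth unchanged
  cfg0 <- sim_config(n_genes = 400, n_cells_per_condition = 100,
                     n_markers_per_type = 5, n_time_genes = 30,
                     n_de_genes = 0, mutant_shift = 0, mutant_arrest = Inf,
                     seed = 11)
  sim <- simulate_dataset(cfg0, "MUT35")
  tr2 <- apply_genotype_effect(sim$truth, cfg0)
  expect_equal(tr2$true_latent_time, sim$truth$true_latent_time)
  expect_equal(nrow(tr2$de_gene_truth), 0)

  # inverted phenotype is a configuration error
  cfg_bad <- cfg
  cfg_bad$mutant_arrest <- 9.2  # below early mean + shift
  expect_error(simulate_dataset(cfg_bad, "MUT70"), "invert the phenotype")
})

test_that("marker sets are disjoint and recorded in the truth matrix", {
  cfg <- sim_config(n_genes = 500, n_cells_per_condition = 50,
                    n_markers_per_type = 10, n_time_genes = 20,
                    n_de_genes = 10, seed = 9)
  sim <- simulate_dataset(cfg, "WT35")
  mm <- sim$truth$marker_matrix_truth
  expect_true(all(rowSums(mm) <= 1))           # disjoint programs
  expect_equal(sum(mm), 8 * 10)
  expect_equal(sim$truth$de_marker_overlap, character(0))
  mut <- simulate_dataset(cfg, "MUT35")
  expect_equal(nrow(mut$truth$de_gene_truth), 10)
  expect_setequal(unique(abs(mut$truth$de_gene_truth$log2fc)), 1)
})
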