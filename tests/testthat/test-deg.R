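# small normalized matrix straight from a dense value matrix
nm_from_values <- function(x) {
  normalized_matrix(
    methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                            "CsparseMatrix"), "generalMatrix"),
    data.frame(barcode = colnames(x), row.names = colnames(x)),
    provenance = list(scale_factor = 1e4, log_base = "e"))
}

test_that("the exact Wilcoxon path reproduces enumerated p-values", {
  # {1,2,3} vs {4,5,6}: all 20 rank assignments -> two-sided p = 0.1
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("G1", paste0("c", 1:6)))
  nm <- nm_from_values(x)
  tab <- deg_wilcoxon(nm, paste0("c", 1:3), paste0("c", 4:6),
                      f = deg_filter(min_abs_log2fc = 0, min_pct = 0))
  expect_equal(tab$p_raw, 0.1, tolerance = 1e-12)
  # agrees with the base-R exact test
  expect_equal(tab$p_raw, wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value)
})

test_that("identical groups produce no fold change and no calls", {
  x <- matrix(rep(c(1, 2, 3, 1, 2, 3), 4), 4, 6, byrow = TRUE,
              dimnames = list(paste0("G", 1:4), paste0("c", 1:6)))
  nm <- nm_from_values(x)
  expect_warning(
    tab <- deg_wilcoxon(nm, paste0("c", 1:3), paste0("c", 4:6)),
    "no genes pass")
  expect_equal(nrow(tab), 0)
})

test_that("Bonferroni adjustment multiplies by the family size", {
  set.seed(99)
  x <- matrix(rexp(100 * 40), 100, 40,
              dimnames = list(sprintf("G%03d", 1:100), paste0("c", 1:40)))
  x[1, 1:20] <- x[1, 1:20] + 3
  nm <- nm_from_values(x)
  tab <- deg_wilcoxon(nm, paste0("c", 1:20), paste0("c", 21:40),
                      f = deg_filter(min_abs_log2fc = 0, min_pct = 0))
  expect_equal(attr(tab, "n_tests"), 100)
  expect_equal(tab$p_adj, pmin(1, tab$p_raw * 100))
  # the worked arithmetic: p 0.0004 with 100 genes tested -> 0.04
  expect_equal(min(1, 0.0004 * 100), 0.04)
  # adjust over tested subset by flag
  tab2 <- deg_wilcoxon(nm, paste0("c", 1:20), paste0("c", 21:40),
                       f = deg_filter(min_abs_log2fc = 0.25, min_pct = 0.1),
                       adjust_over = "tested")
  expect_equal(tab2$p_adj, pmin(1, tab2$p_raw * attr(tab2, "n_tests")))
  expect_lt(attr(tab2, "n_tests"), 100)
})

test_that("group swap negates log2fc and preserves p exactly", {
  set.seed(7)
  x <- matrix(rexp(50 * 60, rate = 0.7), 50, 60,
              dimnames = list(sprintf("G%02d", 1:50), paste0("c", 1:60)))
  nm <- nm_from_values(x)
  g1 <- paste0("c", 1:30); g2 <- paste0("c", 31:60)
  f <- deg_filter(min_abs_log2fc = 0, min_pct = 0)
  a <- deg_wilcoxon(nm, g1, g2, f)
  b <- deg_wilcoxon(nm, g2, g1, f)
  a <- a[order(a$gene), ]; b <- b[order(b$gene), ]
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)
  expect_equal(a$pct1, b$pct2)
})

test_that("normal approximation tracks exact enumeration at n = 20", {
  set.seed(20)
  for (rep in 1:20) {
    v <- round(rnorm(20), 3)               # continuous, no ties
    x <- matrix(v, 1, 20, dimnames = list("G1", paste0("c", 1:20)))
    p_exact <- organoidDev:::.ranksum_p_exact(v[1:10], v[11:20])
    p_approx <- organoidDev:::.ranksum_p_approx(x, 1:10, 11:20)
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("injected genotype effects are recovered with controlled errors", {
  cfg <- two_group_config(5)
  wt <- simulate_dataset(cfg, "WT35")
  mut <- simulate_dataset(cfg, "MUT35")
  nm <- lognormalize(merge_counts(list(drop_mt_genes(wt$counts),
                                       drop_mt_genes(mut$counts))))
  tab <- deg_wilcoxon(nm, mut$counts$cell_ids, wt$counts$cell_ids)
  sig <- deg_significant(tab)
  injected <- mut$truth$de_gene_truth$gene
  expect_gte(length(intersect(sig, injected)) / length(injected), 0.8)
  expect_lte(length(setdiff(sig, injected)), 2)
  # direction: MUT as group 1, up-injected genes come out positive
  up <- mut$truth$de_gene_truth$gene[mut$truth$de_gene_truth$log2fc > 0]
  got <- tab[tab$gene %in% up, ]
  expect_true(all(got$log2fc > 0))
})

test_that("set accounting performs exact Venn arithmetic", {
  acc <- deg_set_accounting(list(a = c("a", "b", "c"), b = c("b", "c", "d")))
  expect_equal(unname(acc$sizes), c(3, 3))
  expect_equal(acc$pairwise["a", "b"], 2)
  expect_equal(unname(acc$exclusive), c(1, 1))
  acc2 <- deg_set_accounting(list(x = c("p", "q"), y = c("p", "q")))
  expect_equal(acc2$pairwise["x", "y"], 2)
  expect_equal(unname(acc2$exclusive), c(0, 0))
  # inclusion-exclusion holds on random sets
  set.seed(1)
  universe <- sprintf("g%04d", 1:1000)
  sets <- lapply(1:3, function(i) sample(universe, 100))
  names(sets) <- c("s1", "s2", "s3")
  acc3 <- deg_set_accounting(sets)
  union_size <- length(unique(unlist(sets)))
  incl_excl <- sum(acc3$sizes) -
    (acc3$pairwise["s1", "s2"] + acc3$pairwise["s1", "s3"] +
     acc3$pairwise["s2", "s3"]) + acc3$common_all
  expect_equal(union_size, incl_excl)
  expect_error(deg_set_accounting(list(a = "x")), "at least 2")
})

test_that("composition tables respect the simplex constraint", {
  comp <- composition(c(rep("NB", 30), rep("glia", 70)), rep("WT35", 100))
  expect_equal(comp$percent[comp$type == "NB"], 30)
  expect_equal(comp$percent[comp$type == "glia"], 70)
  set.seed(2)
  types <- sample(c("a", "b", "c"), 500, replace = TRUE)
  conds <- sample(c("x", "y"), 500, replace = TRUE)
  comp2 <- composition(types, conds)
  sums <- as.numeric(tapply(comp2$percent, comp2$condition, sum))
  expect_equal(sums, c(100, 100), tolerance = 1e-9)
})

test_that("simulated compositions are recovered within binomial error", {
  cfg <- sim_config(n_genes = 300, n_cells_per_condition = 2500,
                    n_markers_per_type = 5, n_time_genes = 20,
                    n_de_genes = 0, seed = 29)
  sim <- simulate_dataset(cfg, "WT35")
  comp <- composition(sim$truth$true_type,
                      sim$counts$cell_meta$condition)
  p_cfg <- cfg$type_proportions["WT35", ]
  n <- 2500
  ok <- vapply(names(p_cfg), function(ty) {
    p_hat <- comp$count[comp$type == ty] / n
    abs(p_hat - p_cfg[ty]) <= 1.96 * sqrt(p_cfg[ty] * (1 - p_cfg[ty]) / n)
  }, logical(1))
  expect_gte(sum(ok), 7)   # 8 simultaneous 95% intervals
})

test_that("Kruskal-Wallis matches its closed-form H with printed stars", {
  kw <- kruskal_wallis_by_group(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_equal(kw$stars, p_stars(kw$p))

  # degenerate all-identical input
  kw0 <- kruskal_wallis_by_group(list(c(1, 1), c(1, 1)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)

  # two groups: chi-square equivalence with the rank-sum z (no continuity)
  set.seed(11)
  for (rep in 1:10) {
    v <- rpois(30, 3)
    x <- matrix(v, 1, 30, dimnames = list("G", paste0("c", 1:30)))
    p_kw <- kruskal_wallis_by_group(list(v[1:15], v[16:30]))$p
    p_z <- organoidDev:::.ranksum_p_approx(x, 1:15, 16:30, correct = FALSE)
    expect_equal(p_kw, unname(p_z), tolerance = 1e-10)
  }
  expect_error(kruskal_wallis_by_group(list(1:3)), "at least 2")
})

test_that("star labels follow the printed thresholds", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009, 0.000009)),
               c("ns", "*", "**", "***", "****"))
  # boundary values are not starred at the next level
  expect_equal(p_stars(0.05), "ns")
  expect_equal(p_stars(0.00001), "***")
})
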