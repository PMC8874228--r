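#!/usr/bin/env Rscript
# 05 — Mutant vs wild-type contrasts: Wilcoxon differential expression per
# timepoint with the study's filters (|log2FC| >= 0.25, Bonferroni-adjusted
# p < 0.05, detection >= 10%), DEG set accounting across timepoints, the
# cellular-composition contrast, and Kruskal-Wallis condition tests on the
# strongest genotype-responsive genes.
#
# Requires scratch/03_cell_assignments.tsv from script 03.

suppressPackageStartupMessages(library(organoidDev))
seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
conds <- rownames(cfg$type_proportions)
sims <- lapply(conds, function(cc) simulate_dataset(cfg, cc))
names(sims) <- conds
nm <- qc_normalize(lapply(sims, `[[`, "counts"))
cond <- stats::setNames(nm$cell_meta$condition, nm$cell_ids)

run_contrast <- function(day) {
  mut_cells <- nm$cell_ids[cond == paste0("MUT", day)]
  wt_cells <- nm$cell_ids[cond == paste0("WT", day)]
  deg_wilcoxon(nm, mut_cells, wt_cells)   # MUT is group 1 throughout
}
tab35 <- run_contrast("35")
tab70 <- run_contrast("70")
sig35 <- deg_significant(tab35)
sig70 <- deg_significant(tab70)
acc <- deg_set_accounting(list(day35 = sig35, day70 = sig70))
cat(sprintf("DEGs (p adj < 0.05, |log2FC| > 0.25): day35 = %d, day70 = %d, common = %d\n",
            acc$sizes["day35"], acc$sizes["day70"], acc$pairwise["day35", "day70"]))
truth_de <- sims[["MUT35"]]$truth$de_gene_truth$gene
cat(sprintf("of %d genes with injected genotype effects, %d are recovered at day 35 and %d at day 70\n",
            length(truth_de), length(intersect(sig35, truth_de)),
            length(intersect(sig70, truth_de))))

fmt <- function(tab) transform(tab, log2fc = round(log2fc, 3),
                               pct1 = round(pct1, 3), pct2 = round(pct2, 3))
write.table(fmt(tab35[tab35$p_adj < 0.05, ]), "results/05_deg_day35.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fmt(tab70[tab70$p_adj < 0.05, ]), "results/05_deg_day70.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(set = names(acc$sizes), size = as.integer(acc$sizes),
                       exclusive = as.integer(acc$exclusive),
                       common = acc$pairwise["day35", "day70"]),
            "results/05_deg_overlap.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# composition contrast on the assigned identities from script 03
asg_path <- "scratch/03_cell_assignments.tsv"
if (file.exists(asg_path)) {
  cells <- read.table(asg_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  comp <- composition(cells$assigned_type, cells$condition)
  comp$percent <- round(comp$percent, 2)
  write.table(comp, "results/05_composition_assigned.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  wide <- reshape(comp[, c("condition", "type", "percent")],
                  idvar = "type", timevar = "condition", direction = "wide")
  cat("\nassigned composition (percent per condition):\n")
  print(wide, row.names = FALSE)
} else {
  cat("\nrun analysis/03_cluster_annotate.R first for the composition contrast\n")
}

# Kruskal-Wallis across the four conditions for the top recovered genes
top_genes <- head(intersect(tab70$gene[order(tab70$p_adj)], truth_de), 4)
kw_rows <- lapply(top_genes, function(g) {
  vals <- split(as.numeric(nm$values[g, ]), cond[nm$cell_ids])
  kw <- kruskal_wallis_by_group(vals)
  data.frame(gene = g, H = round(kw$H, 2), df = kw$df,
             p = signif(kw$p, 3), stars = kw$stars)
})
kw_tab <- do.call(rbind, kw_rows)
write.table(kw_tab, "results/05_kruskal_wallis.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nKruskal-Wallis across conditions, top genotype-responsive genes:\n")
print(kw_tab, row.names = FALSE)
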