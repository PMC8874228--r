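#!/usr/bin/env Rscript
# 01 — Generate the synthetic study: four midbrain-organoid conditions
# (WT/LRRK2-mutant at day 35 and 70) and an embryonic reference atlas
# (weeks 6-11), with full ground truth.
#
# The generator is deterministic: every later script rebuilds the same data
# from the same configuration instead of reading intermediates. Large raw
# exports go under scratch/ (not part of the repository); summary tables go
# under results/.

suppressPackageStartupMessages(library(organoidDev))
seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
conds <- rownames(cfg$type_proportions)
sims <- lapply(conds, function(cc) simulate_dataset(cfg, cc))
names(sims) <- conds

summary_tab <- do.call(rbind, lapply(conds, function(cc) {
  s <- sims[[cc]]
  data.frame(condition = cc,
             genotype = unique(s$counts$cell_meta$genotype),
             cells = ncol(s$counts$values),
             genes = nrow(s$counts$values),
             doublets = sum(s$truth$doublet_flags),
             median_counts = median(s$counts$cell_meta$total_counts),
             median_features = median(s$counts$cell_meta$n_features),
             median_mt_pct = round(100 * median(s$counts$cell_meta$mt_fraction), 2))
}))
write.table(summary_tab, "results/01_simulation_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(summary_tab, row.names = FALSE)

# true composition per condition (the design the pipeline must recover)
truth_comp <- do.call(rbind, lapply(conds, function(cc) {
  comp <- composition(sims[[cc]]$truth$true_type,
                      rep(cc, length(sims[[cc]]$truth$true_type)))
  comp$percent <- round(comp$percent, 2)
  comp
}))
write.table(truth_comp, "results/01_true_composition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# the binarized marker matrix used for annotation downstream
write_marker_matrix(truth_marker_matrix(sims[[1]]$truth),
                    "results/01_marker_matrix.csv")

# one full dataset in exchange format (MTX + TSV), as an interface example
write_dataset(sims[["WT35"]]$counts, "scratch/WT35")
write_truth(sims[["WT35"]]$truth, "scratch/WT35_truth.json")
cat("\nwrote results/01_* and scratch/WT35/\n")
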