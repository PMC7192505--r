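#!/usr/bin/env Rscript
# Noise analyses: the random-guessing AUC null at the cohort sizes used by
# clinical series (24 to 169 patients), and a gene-label permutation null
# for a representative pipeline on the simulated data.

suppressMessages(library(tmscan))

seed <- 20260930L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

splits <- list(n24 = c(rep(1L, 10), rep(0L, 14)),
               n25 = c(rep(1L, 13), rep(0L, 12)),
               n39 = c(rep(1L, 20), rep(0L, 19)),
               n169 = c(rep(1L, 85), rep(0L, 84)))
null_summary <- do.call(rbind, lapply(names(splits), function(nm) {
  nd <- random_response_null(splits[[nm]], n_draws = 10000, seed = seed)
  data.frame(cohort = nm, n = length(splits[[nm]]),
             mean_auc = mean(nd$draws), sd_auc = sd(nd$draws),
             q95 = unname(quantile(nd$draws, 0.95)))
}))
utils::write.table(null_summary, file.path(out, "random_null.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("random-guessing null (10,000 draws each):\n")
print(null_summary, row.names = FALSE, digits = 3)
cat("spread shrinks with cohort size: the same AUC is far less",
    "remarkable in a 24-patient series than in a 169-patient one\n\n")

sim <- generate_paired_datasets(simulation_params(
  n_genes = 200, n_signal_genes = 20, n_housekeeping = 40,
  n_landmark = 40, n_cell_lines = 300, n_patients = 30,
  effect_size = 2, batch_shift_sd = 0, batch_scale_sd = 0,
  seed = seed))
cfg <- enumerate_grid("drug01", "none", "limma", "all", "none", "linear")
perm <- permuted_gene_null(cfg, sim$screen, sim$cohort, n_perm = 100,
                           seed = seed,
                           control = black_box_control(rf_trees = 50,
                                                       ranger_trees = 100))
real <- run_pipeline(cfg[1, ], sim$screen, sim$cohort)$auc_roc
utils::write.table(data.frame(perm_auc = perm[, 1]),
                   file.path(out, "permutation_null.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("gene-permutation null (100 permutations):\n")
cat("  real AUC:", round(real, 3), " null 95th percentile:",
    round(quantile(perm[, 1], 0.95), 3), "\n")
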