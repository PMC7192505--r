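#!/usr/bin/env Rscript
# Generate the synthetic study data: a multi-drug cell-line screen paired
# with a small patient cohort that carries a train-vs-test batch shift.
# Writes the expression matrices, response tables and ground truth under
# results/data/.

suppressMessages(library(tmscan))

seed <- 20260930L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

params <- simulation_params(n_genes = 500, n_signal_genes = 40,
                            n_housekeeping = 80, n_landmark = 80,
                            n_cell_lines = 200, n_patients = 30,
                            n_drugs = 6, seed = seed)
sim <- generate_paired_datasets(params)

write_expression_matrix(sim$screen$expression,
                        file.path(out, "screen_expression.tsv"))
write_expression_matrix(sim$cohort$expression,
                        file.path(out, "cohort_expression.tsv"))
utils::write.table(data.frame(drug = rownames(sim$screen$response),
                              sim$screen$response, check.names = FALSE),
                   file.path(out, "screen_response.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
writeLines(sim$screen$landmark_genes, file.path(out, "landmark_genes.txt"))
writeLines(sim$screen$housekeeping_genes,
           file.path(out, "housekeeping_genes.txt"))
jsonlite::write_json(
  list(response = as.list(sim$cohort$response),
       truth = list(signal_genes = sim$truth$signal_genes,
                    administered_drug = sim$truth$administered_drug),
       params = unclass(params)),
  file.path(out, "cohort.json"), auto_unbox = TRUE, pretty = TRUE)

cat("screen:", nrow(sim$screen$expression), "genes x",
    ncol(sim$screen$expression), "cell lines,",
    nrow(sim$screen$response), "drugs\n")
cat("cohort:", ncol(sim$cohort$expression), "patients,",
    sum(sim$cohort$response), "responders\n")
cat("per-gene batch shift sd:", round(sd(sim$truth$batch_shift), 3), "\n")
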