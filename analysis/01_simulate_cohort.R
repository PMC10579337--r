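#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs with known ground truth:
#   (a) a small panel of multichannel imaging fields (written as TIFF +
#       truth CSVs) for the image-quantification stage,
#   (b) a cohort-scale per-field CA-score table drawn from the copula
#       mixed model (two cohorts, FT controls + tumours),
#   (c) an expression matrix with a planted CA20 signal,
#   (d) copy-number-signature compositions with a planted ALR shift.
# Everything derives from one root seed through named substreams.

suppressMessages({library(centramp); library(dplyr)})
root_seed <- 20260924L
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)
# stacks are large binaries -> scratch/; tables and truth stay in results/
dir.create("scratch/simulated_fields", showWarnings = FALSE, recursive = TRUE)

## (a) imaging fields: one well of 5 fields, plus 3 noisy fields
message("Simulating imaging fields...")
cfg <- image_sim_config(seed = substream_seed(root_seed, "images"))
well <- simulate_cellline_well(cfg, n_fields = 5L)
for (i in seq_along(well)) {
  write_field_tiff(well[[i]]$stack,
                   sprintf("scratch/simulated_fields/field_%02d.tif", i))
  write_truth_tables(well[[i]]$truth,
                     sprintf("results/simulated/field_%02d", i))
}
write_sim_config(cfg, "results/simulated/image_config.yml")
message("  wrote 5 noise-free fields (stacks + truth tables)")

## (b) cohort CA table from the copula LMM (log scale -> CA scores)
message("Simulating cohort CA-score table from the mixed model...")
params <- copula_lmm_params(beta = c(0, 0.9), tau = 0.3, gamma = c(-1, 0.4),
                            alpha = 4, rho = 0.5, nu = 8)
build_cohort <- function(cohort, n_ft, n_tum, seed) {
  des <- two_group_design(n_ft, n_tum, 25L)
  y <- simulate_ca_dataset(params, des, seed = seed)
  tibble(sample = paste0(cohort, "_", y$tissue_id),
         patient = paste0(cohort, "_P",
                          (match(y$tissue_id, unique(y$tissue_id)) + 1L) %/% 2L),
         cohort = cohort,
         tissue_type = ifelse(grepl("^FT", y$tissue_id), "normal-FT", "tumour"),
         field = y$field,
         # back to the CA-score scale; cohort-specific staining batch factor
         ca_score = exp(y$y) * ifelse(cohort == "OV04", 0.30, 0.42))
}
tab <- bind_rows(build_cohort("OV04", 8L, 16L, substream_seed(root_seed, "ov04")),
                 build_cohort("BriTROC", 8L, 16L, substream_seed(root_seed, "britroc")))
write_field_table(tab, "results/simulated/cohort_fields.csv")
message(sprintf("  %d fields across %d samples", nrow(tab),
                length(unique(tab$sample))))

## (c) expression with planted CA20 signal
expr <- simulate_expression_matrix(60L, planted_effect = 1, noise_sd = 0.5,
                                   seed = substream_seed(root_seed, "expr"))
write.csv(expr$matrix, "results/simulated/expression_log2.csv")
writeLines(expr$labels, "results/simulated/expression_truth_labels.txt")

## (d) signature compositions with a planted shift
comp <- simulate_signature_compositions(
  30L, alr_shift = c(0.6, -0.4, 0.3, 0, 0, 0), concentration = 25,
  seed = substream_seed(root_seed, "cns"))
write.csv(cbind(group = as.character(comp$group), as.data.frame(comp$exposures)),
          "results/simulated/cns_exposures.csv", row.names = TRUE)
message("Stage 1 complete: inputs + ground truth under results/simulated/")
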