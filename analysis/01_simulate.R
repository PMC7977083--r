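#!/usr/bin/env Rscript
# Generate the synthetic datasets used throughout the analysis:
#  - the default 5000-gene QC design (planted low-depth and
#    satellite-contaminated cells, per-cell depth matching the study's
#    ~44,500 UMIs per neuron),
#  - the 166-cell clustering benchmark (cluster proportions 51/31/28/28/28,
#    twenty 4-fold markers per cluster on a 2000-gene panel),
#  - a 4-stage developmental time course in which the adult subtype program
#    decays toward earlier stages.
# Everything is written under results/data/ as MTX + TSV sidecars and JSON
# ground truth.

library(modclust)
seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

qc_sim <- simulate_counts(synthetic_spec(seed = seed))
write_counts(qc_sim$counts, file.path(out, "qc_design", "counts.mtx"))
write_truth(qc_sim$truth, file.path(out, "qc_design_truth.json"))
cat(sprintf("QC design: %d genes x %d cells (%d low-depth, %d contaminated planted)\n",
            nrow(qc_sim$counts$counts), ncol(qc_sim$counts$counts),
            length(qc_sim$truth$flagged_lowdepth),
            length(qc_sim$truth$flagged_contaminant)))

bench <- simulate_counts(benchmark_spec(seed = seed))
write_counts(bench$counts, file.path(out, "benchmark", "counts.mtx"))
write_truth(bench$truth, file.path(out, "benchmark_truth.json"))
clean <- setdiff(bench$counts$cell_ids,
                 c(bench$truth$flagged_lowdepth,
                   bench$truth$flagged_contaminant))
cat(sprintf("benchmark: %d cells (%d clean), planted cluster sizes %s\n",
            ncol(bench$counts$counts), length(clean),
            paste(table(bench$truth$cell_labels[clean]), collapse = "/")))

mk_stage <- function(s) synthetic_spec(
  n_genes = 400, cluster_sizes = c(50, 50),
  marker_genes_per_cluster = 10, marker_fold_change = 4,
  marker_off_scale = 0.05, n_contaminant_cells = 0,
  n_lowdepth_cells = 0, seed = s)
tc <- simulate_timecourse(lapply(seed + 201:204, mk_stage),
                          coexpression_decay = 0.5,
                          stage_names = c("e14", "p0", "p12", "adult"))
for (stage in names(tc))
  write_counts(tc[[stage]]$counts,
               file.path(out, paste0("stage_", stage), "counts.mtx"))
write_truth(tc$adult$truth, file.path(out, "timecourse_adult_truth.json"))
cat("time course:", length(tc), "stages x", ncol(tc[[1]]$counts$counts),
    "cells\n")
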