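#!/usr/bin/env Rscript
# Cell-level quality control on the simulated plate-seq dataset: the
# gene-detection floor (>= 2000 detected genes) and the satellite-cell
# contamination filter (Mbp CPM < 10,000 and Apoe CPM < 20), followed by
# CPM normalization. Both published contamination dialects are evaluated
# and compared against the planted ground truth.

library(modclust)

sim <- read_counts("results/data/qc_design/counts.mtx")
truth <- jsonlite::read_json("results/data/qc_design_truth.json",
                             simplifyVector = TRUE)

report <- suppressWarnings(qc_metrics(sim))
filtered <- filter_cells(sim, report)
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write_qc_report(report, "results/qc/qc_report.tsv")
writeLines(filtered$removed$lowdepth, "results/qc/removed_lowdepth.txt")
writeLines(filtered$removed$contaminated,
           "results/qc/removed_contaminated.txt")

cat(sprintf("removed %d low-depth and %d contaminated of %d cells; %d kept\n",
            length(filtered$removed$lowdepth),
            length(filtered$removed$contaminated),
            ncol(sim$counts), ncol(filtered$kept$counts)))
cat(sprintf("low-depth recovery exact: %s; contamination recovery exact: %s\n",
            setequal(filtered$removed$lowdepth, truth$flagged_lowdepth),
            setequal(filtered$removed$contaminated,
                     truth$flagged_contaminant)))
cat(sprintf("both dialects agree on %d/%d cells\n",
            sum(report$pass_contamination_methods ==
                  report$pass_contamination_main_text), nrow(report)))
cat(sprintf("kept cells: mean %.0f UMIs, %.0f detected genes per cell\n",
            mean(colSums(filtered$kept$counts)),
            mean(colSums(filtered$kept$counts > 0))))
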