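#!/usr/bin/env Rscript
# Two-dimensional embedding of the benchmark cells: all pairwise-DE genes
# (BH-adjusted p < 0.05), log10(CPM + 1), top 20 principal components,
# t-SNE layout with a fixed seed. Cells are never clustered in the
# embedding; it is display only.

library(modclust)

sim <- read_counts("results/data/benchmark/counts.mtx")
clusters <- read.delim("results/cluster/clusters.tsv")
labels <- stats::setNames(clusters$cluster, clusters$cell_id)
kept <- subset_cells(sim, names(labels))
norm <- suppressWarnings(cpm_normalize(kept))

de <- all_pairs_de(kept, labels)
emb <- embed_cells(norm, de, n_pcs = 20, seed = 1)
dir.create("results/embedding", showWarnings = FALSE, recursive = TRUE)
write.table(cbind(as.data.frame(emb$coords),
                  cluster = labels[rownames(emb$coords)]),
            "results/embedding/tsne.tsv", sep = "\t", quote = FALSE,
            col.names = NA)
cat(sprintf("embedded %d cells on %d DE genes (%d PCs)\n",
            nrow(emb$coords), length(emb$de_genes), ncol(emb$pcs)))
cat("coordinates in results/embedding/tsne.tsv\n")
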