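# modclust

Cell-type discovery for small, deep, plate-based single-cell RNA-seq
datasets — the regime used to resolve proprioceptor (muscle spindle and
Golgi tendon organ afferent) subtypes among a few hundred FACS-sorted
dorsal root ganglion neurons sequenced to ~45,000 UMIs each.

The package implements the full analysis as a tested, reusable workflow:

1. **Quality control**: remove cells with < 2000 detected genes and cells
   contaminated by attached satellite glia, using either published
   filtering dialect (Mbp CPM < 10,000 & Apoe CPM < 20, or > 10% of the
   mean Apoe/Mpz transcript level), then CPM-normalize
   (counts / cell total × 10⁶).
2. **Iterative gene-module clustering**: in each cell scope, take the top
   Fano-factor genes, detect WGCNA-style co-expression modules (adjacency
   |r|^power, power 1, average linkage, single-height cut with ceiling
   0.995), keep modules with co-expression beyond chance (permutation
   test) that define transcriptionally distinct cell splits, split cells
   by Ward clustering on eigengene correlations, merge candidate clusters
   whose pairwise moderated-t DE score Σ min(−log₁₀ p, 20) falls below
   100, and recurse until no structure remains.
3. **Bootstrap consensus**: repeat the whole recursion 100× on random 80%
   cell subsets, build the cell–cell co-clustering matrix, merge reference
   clusters with mean co-clustering > 0.25, and repair boundary cells by
   majority vote.
4. **Markers and enrichment**: all-pairs moderated-t DE (BH-adjusted),
   binary on/off marker selection (detected in ≥ 70% of one cluster's
   cells, ≤ 20% of another's, significant in ≥ 2 pairs), and classic +
   elim Fisher gene-set enrichment with the ≥ 5-overlap and adjusted
   p < 0.01 filters.
5. **Longitudinal panels**: per-stage Pearson correlation of log(CPM + 1)
   for adult marker genes, ordered by average-linkage clustering of the
   adult matrix, quantifying how subtype co-expression strengthens across
   development (e14.5 → p0 → p12 → adult).
6. **Embedding**: t-SNE of the top 20 PCs of log₁₀(CPM + 1) over all DE
   genes, display only.

A negative-binomial synthetic-data generator with complete planted ground
truth (clusters in the published 51/31/28/28/28 proportions, marker
programs, satellite-contaminated admixture cells, low-depth cells,
developmental decay of marker co-expression) makes every stage testable
without any data download. See `vignettes/methods.Rmd` for the statistical
model, parameter rationale, and known limitations.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R`, then `02`…`06`), writing tables
under `results/`. Their printed output on the bundled designs:

```
QC design: 5000 genes x 184 cells (10 low-depth, 8 contaminated planted)
removed 10 low-depth and 8 contaminated of 184 cells; 166 kept
low-depth recovery exact: TRUE; contamination recovery exact: TRUE
kept cells: mean 46752 UMIs, 4827 detected genes per cell

final clusters: 5 (5 major), sizes 51/31/28/28/28
adjusted Rand index vs planted truth: 1.000

selected 32 binary markers; precision vs planted map 1.000
enrichment of genes up in cluster C1 vs C2:
         set overlap    p_classic       p_elim passes_filters
          C1      12 5.118125e-28 5.118125e-28           TRUE
 program_1_2      12 1.384021e-21 1.000000e+00          FALSE

mean within-module |r| by stage:
  e14    p0   p12 adult
0.111 0.156 0.458 0.780
```

Reading this: quality control recovers exactly the planted low-depth and
contaminated cells; the iterative clustering plus 25×80% bootstrap
consensus reports exactly the five planted subtypes with perfect
agreement (ARI 1.0); binary marker selection returns only planted marker
genes; the elim enrichment pass finds the specific program (C1) and
correctly discounts its general parent term after removing the child's
genes; and marker co-expression strengthens monotonically toward the
adult stage, the signature of an adult-locked subtype program.

In code, the core loop is:

```r
library(modclust)
sim    <- simulate_counts(benchmark_spec(seed = 1))
report <- qc_metrics(sim$counts, min_genes = 1000)
kept   <- filter_cells(sim$counts, report)$kept
result <- run_pipeline(sim$counts, benchmark_config(seed = 1))
table(result$assignment$labels)   # 51 31 28 28 28
```

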