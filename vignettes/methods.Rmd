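---
title: "Iterative gene-module clustering for deep plate-based scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative gene-module clustering for deep plate-based scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

modclust implements a cell-type discovery workflow for small, deep,
plate-based single-cell RNA-seq datasets of sorted neuron populations —
the regime of a few hundred FACS-sorted cells sequenced to tens of
thousands of UMIs each, as used to resolve proprioceptor subtypes in adult
mouse dorsal root ganglia. This vignette explains the statistical model
behind each stage, the tunable parameters and their defaults, what the
bundled synthetic-data generator does and does not emulate, and the design
choices made where the procedure was genuinely open.

## Quality control and normalization

Cells are filtered on two published rules. First, gene detection: cells
with fewer than `min_genes = 2000` detected genes (count > 0) are removed.
Second, satellite-cell contamination: sensory neurons are ensheathed by
satellite glia, and incompletely dissociated cells carry glial transcripts
(Apoe, Mpz, Mbp). Two dialects of the contamination rule exist in the
source protocol and both are implemented:

* **methods** (default): keep a cell iff Mbp CPM < 10,000 *and* Apoe
  CPM < 20. Fully specified thresholds.
* **main_text**: remove a cell if its summed raw Apoe + Mpz count exceeds
  10% of the dataset mean of that sum.

The dialects can disagree on real data; which one produced the published
removal counts is not recorded, so the choice is a config switch
(`qc$contamination_dialect`) and neither is claimed to reproduce the
original code. The detection rule is applied first, the contamination rule
to its survivors, so the reported removal counts are unambiguous.

Normalization is counts-per-million: each cell's counts are divided by its
total UMI count and scaled by $10^6$. Zero-depth cells are left as
all-zero columns with a warning and always fail QC. Downstream analyses
use $\log_{10}(\mathrm{CPM}+1)$ for clustering and differential
expression, and $\ln(\mathrm{CPM}+1)$ for the longitudinal correlation
panels, following the respective conventions of each analysis; Pearson
correlation is invariant to the log base, so the distinction is cosmetic.

## High-variance gene selection

Each clustering scope starts from the genes with the highest Fano factor
(sample variance over mean of CPM, denominator $n-1$; zero-mean genes
excluded, ties broken by gene id). The default `n_top_genes = 6000`
corresponds to a whole-transcriptome matrix with roughly 15,000 detected
genes, i.e. the top ~40%. For the bundled 2000-gene benchmark panel the
same fraction is 800 genes (`benchmark_config()`); keeping the fraction
rather than the absolute count matters because the low-expression tier
contributes technical covariation (below) that Fano ranking pushes down
the list.

## Gene modules

Co-expression modules are detected WGCNA-style: adjacency
$a_{ij} = |r_{ij}|^{\beta}$ with soft power $\beta = 1$ on
$\log_{10}(\mathrm{CPM}+1)$, distance $1-a$, average-linkage hierarchical
clustering, and a single-height tree cut with ceiling
`cutheight = 0.995`.

A literal flat cut at 0.995 deserves comment. With $n$ cells the absolute
correlation of unrelated genes concentrates near
$r_0 = \sqrt{2/\pi(n-1)}$ — about 0.06 at 166 cells — so *every*
average-linkage merge happens below height $1 - r_0 \approx 0.94$ and a
static cut at 0.995 returns the entire gene set as one block whose
eigengene is noise. The 0.995 figure is only meaningful as the ceiling of
a branch-sensitive cut. The default method therefore places the single cut
at $h^* = \min(0.995,\, 1 - c\,r_0)$ with `coherence_factor` $c = 5$,
which converges to the literal 0.995 as the cell count grows, and then
refines branches in the manner of WGCNA module assignment:

1. branches of at least 3 genes at a permissive height seed candidate
   modules. Seeding clusters the *signed* correlation distance
   $1 - \mathrm{sign}(r)|r|^\beta$: the marker programs of mutually
   exclusive subtypes anti-correlate well above noise, so on the unsigned
   scale two such programs share one branch — from which the membership
   refinement can keep only one — while with sign they are maximally
   distant;
2. every gene is re-assigned to the module whose mean expression profile
   it correlates with best, with a module's own members scored against the
   profile of the *other* members (leave-one-out) — without this, any seed
   sustains itself, because a gene always correlates with a summary it
   contributed to;
3. modules with near-parallel eigengenes (|cor| > 0.75, the WGCNA
   close-module merging convention on the unsigned scale) are merged —
   this deliberately unifies anti-correlated programs, e.g. the markers of
   two mutually exclusive subtypes, whose joint eigengene is exactly the
   axis separating them;
4. surviving modules must reach mean |r| of at least
   $\min(0.3,\ c\,r_0)$ and `min_module_size = 10` genes. The absolute cap
   of 0.3 keeps small cell scopes testable ($c\,r_0$ exceeds 0.5 below
   ~60 cells, which no real module could reach), while genuine subtype
   programs in this data regime sit at mean |r| ≈ 0.35–0.8 and technical
   tiers below ~0.25.

The literal static cut remains available (`method = "static"`), as does an
optional topological-overlap transform (`use_tom`, default off).

Two independent guards then decide whether a scope has structure at all:

* **Permutation significance** (`module_significance`): the coherence
  statistic (mean within-module |r|) is compared with a null built by
  independently permuting each gene across cells, `n_perm = 100` times;
  a module is kept iff its statistic exceeds the null's 95th percentile,
  and $p = (1+\#\{null \ge obs\})/(1+n_{perm})$ is reported. For modules
  above `max_stat_genes = 200` genes the statistic (observed and null
  alike) is computed on a fixed random subset, keeping the test
  $O(200^2 n)$; the test is exact for the subsampled statistic.
* **Split validation** (`validate_modules`): the permutation test cannot
  see *selection* bias — a module assembled by searching thousands of
  genes for mutually correlated sets carries inflated sample correlations
  that permutation cannot explain away. Each module is therefore also
  required to do the job the pipeline needs modules for: cells are split
  by an exact two-means partition of the module eigengene and the split
  must reach the same summed $-\log_{10} p$ DE score used for cluster
  merging (threshold 100, below). Noise-selected modules score near 0,
  genuine subtype programs score in the hundreds.

Module eigengenes are the first principal component of the gene-wise
z-scored $\log_{10}(\mathrm{CPM}+1)$ submatrix, unit-variance and
sign-oriented so correlation with the module mean profile is nonnegative;
zero-variance genes are dropped with a warning.

## Iterative splitting and merging

Within a scope, cells are clustered by Ward linkage on the distance
$1 - r$ between their eigengene vectors, cut at
$k = \min(k_{max}, \lfloor n/\text{min\_cluster\_size} \rfloor)$ with
`k_max = 4` and `min_cluster_size = 4`; undersized clusters are reabsorbed
into the cluster with the highest mean correlation. With fewer than three
eigengenes the cell-cell correlation is degenerate (for two eigengenes it
is exactly ±1), so Euclidean distance on the eigengene coordinates is used
instead. The Ward-on-correlation-distance combination treats the distance
as squared-Euclidean compatible; this is the stated procedure, kept as an
approximation.

Candidate clusters are then merged by differential expression: for each
pair, a moderated-t test (below) is run, DE genes are those with
BH-adjusted $p < 0.05$ and $|\log_2 FC| \ge 1$, and the pair's score is
$\sum \min(-\log_{10} p_{raw}, 20)$ over DE genes. Pairs scoring below
`merge_threshold = 100` are merged, smallest score first, with
recomputation after every merge. The per-gene cap of 20 stops a single
ultra-significant gene from carrying a pair on its own. The procedure
recurses into each surviving cluster until a scope yields no validated
modules or no split survives merging. Terminal clusters under 15 cells are
flagged *minor*; they are reported, excluded from marker analysis by
default, and never deleted.

`k_max = 4` is this package's choice (the source procedure does not state
how many candidates each cut produces); over-splitting is tolerated by
design because the merge step and the consensus stage below are the
guards. Each recursion scope draws its RNG seed from a deterministic
counter, so the full recursion is reproducible bit-for-bit.

## Bootstrap consensus

The full recursion is repeated `n_iter = 100` times on random 80% subsets
of cells (run $i$ seeded with $seed + i$). The co-clustering matrix
records, for every cell pair, the fraction of runs sampling both in which
they landed in the same cluster; pairs never co-sampled are missing, not
imputed. Reference clusters (one full-data run with the master seed) are
merged while any pair's mean co-clustering over defined cross-cluster
entries exceeds 0.25 — strictly greater, so a mean of exactly 0.25 stays
split. What the original 100-run consensus merged is not recorded; merging
a full-data reference run is the common practice for this algorithm family
and is the documented choice here.

After merging, each cell is re-assigned to the cluster whose members it
co-clusters with most (synchronous majority vote, at most 3 passes,
ties keep the current label). A single reference run occasionally places
boundary cells on the wrong side of an early split and the recursion can
never move them back; the bootstrap matrix holds exactly the information
needed to repair this, and the refinement uses it without changing the
merge rule. Setting `reassign_iters = 0` recovers the bare merge.

## Differential expression and markers

The merge score and the marker analysis share one self-contained
moderated-t test on $\log_2(\mathrm{CPM}+1)$: gene-wise pooled variances
$s^2$ ($d$ residual df) are shrunk toward the median gene variance $s_0^2$
with prior df $d_0 = 4$,
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and the statistic is
referred to $t_{d_0+d}$. $d_0 = 0$ recovers the ordinary pooled t-test
(verified against `t.test` in the suite); $d_0 \to \infty$ pools all genes
to the prior. The original analysis used edgeR (markers) and limma (merge
scores); a single documented test keeps the pipeline self-consistent and
testable, and no equivalence to the negative-binomial GLM is claimed.

Subtype markers mirror the published display rule: genes significantly DE
(adjusted $p < 0.05$, $|\log_2 FC| \ge 1$) in at least 2 cluster pairs
*and* binary on/off — detected in at least 70% of cells of some cluster
and at most 20% of cells of another (`tau_on`/`tau_off`, configurable
operationalizations of the figure legend's qualitative rule), ranked by
number of significant pairs then maximum |log2 FC|.

Gene-set enrichment takes user-supplied collections (GMT plus an optional
two-column parent table); no GO database is bundled. The classic test is
the one-sided hypergeometric; the elim variant processes sets
children-before-parents and, when a set's raw p falls below 0.01, removes
its annotated study genes from all ancestors before they are tested, so
specific terms are not recounted at general ones. Reported sets must
overlap the study list by at least 5 genes and have both BH-adjusted p
values below 0.01; sets annotating fewer than `node_size = 5` genes are
skipped. The published "related to neurons" filter was manual and is
replaced by an optional user keep-list.

## Longitudinal correlation panels

For a chosen gene list (typically adult markers), each developmental
stage contributes a Pearson correlation matrix of $\ln(\mathrm{CPM}+1)$
over that stage's cells, all displayed in the gene order given by
average-linkage clustering of the adult matrix. The per-stage summary is
the mean |r| over within-module gene pairs; on data with an adult-locked
subtype program it increases monotonically toward the adult stage.
Zero-variance genes are recorded with r = 0 and flagged rather than NaN.

## The synthetic-data generator

`simulate_counts()` emulates the statistical structure the pipeline
assumes, with complete planted truth:

* **Counts**: negative binomial with mean $\ell_c \lambda_{gc}$ and
  variance $\mu + \phi\mu^2$ (`nb_dispersion` $\phi = 0.3$ by default;
  $\phi = 0$ is Poisson). Per-cell depth multipliers $\ell_c$ are
  log-normal (σ = 0.3), matching the right-skewed depth of plate data.
* **Depth**: the default 5000-gene design uses `baseline_mean = 9`, giving
  ~45,000 expected UMIs per cell — the published mean depth per neuron
  (44,511). The 166-cell benchmark panel (2000 genes) uses 22 for the same
  per-cell total.
* **Clusters**: default sizes 51/31/28/28/28 (the published 51/166 and
  31/166 proportions), each with 20 disjoint marker genes whose rate is
  multiplied by `marker_fold_change = 4` at home. `marker_off_scale`
  optionally suppresses markers outside the home cluster (0.02 emulates
  binary on/off subtype markers; the default 1 keeps the graded model).
* **Contamination**: contaminated cells are admixtures — the neuronal
  program plus `contaminant_boost` × baseline on Apoe/Mpz/Mbp. Clean cells
  express the glial markers at rate zero; this is what makes exact QC
  recovery a well-posed target at any seed. Real data has ambient glial
  reads in clean cells, which is deliberately not emulated.
* **Low depth**: planted low-depth cells are rescaled (by root-finding on
  the expected detection count) to ~`lowdepth_gene_target` detected genes,
  far below the QC floor; all other cells sit far above it.
* **Time courses**: `simulate_timecourse()` shares the adult stage's gene
  identities, baseline rates and marker map across all stages and
  attenuates the marker program geometrically
  ($f \mapsto f^{\delta^{k}}$ for $k$ steps before the adult, likewise the
  off-state attenuation), so within-module correlation decays toward early
  development. Cells, depths and counts are drawn per stage.

Not emulated: ambient RNA, doublets, batch effects beyond depth, read- or
UMI-level error, and real gene-gene regulatory correlation outside the
planted programs. One technical artifact *is* reproduced faithfully and
matters: dropout-driven covariation — low-depth cells share zeros across
the low-abundance tier, producing genuine mutual correlations (~0.2) among
non-marker genes. The module coherence bar and the split validation are
what keep this tier out of the eigengene space, and passing the bundled
tests shows robustness to this artifact, not to everything real data can
contain.

## Numerical choices and determinism

All randomness flows from explicit integer seeds (`withr::with_seed`;
scope seeds from a deterministic counter, bootstrap run seeds
$seed + i$), so every result in this package is bit-reproducible.
Ties break deterministically throughout (first minimum in merges, stay-put
in majority voting, gene id order in Fano ranking, lower index in
dendrogram leaf order). Degenerate inputs follow documented conventions:
zero-depth cells warn and fail QC, zero-variance genes are dropped from
modules and flagged in correlation panels, clusters under 2 cells score 0
in DE with a warning.

Problem sizes in the test suite and acceptance checks: the clustering
benchmark runs 10 seeds of the full pipeline with 25 bootstrap iterations
(the full protocol's 100 is used by the analysis scripts and the
acceptance script); calibration checks use 2000-gene null panels, 50-seed
type-I error estimates and 100-seed merge-null estimates; oracle
equivalence checks use small instances (30 cells × 5 runs, universes ≤ 25,
10–12 gene modules) where brute force is exact.

## Known limitations

* The moderated t on log-CPM is not edgeR's NB GLM; on strongly
  zero-inflated genes its p values are approximate (the calibration check
  uses a well-expressed panel for exactly this reason).
* The adaptive module cut targets the few-hundred-cell regime; at
  thousands of cells the coherence bar $c\,r_0$ becomes permissive and the
  technical tier may need explicit depth covariates instead.
* Consensus merging can only merge or re-assign; a reference run that
  never separates two subtypes anywhere cannot be rescued by the
  consensus stage.
* The elim enrichment removes only *study* genes from ancestors (the
  documented contract here); topGO's elim removes all annotated genes of a
  significant child, so p values differ in general.
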