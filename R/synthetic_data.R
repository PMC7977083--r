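#' Specification for a synthetic UMI count dataset
#'
#' Defines the generative design for [simulate_counts()]: negative-binomial
#' UMI counts over a set of planted cell clusters with on/off marker
#' programs, log-normal per-cell sequencing depth, optional satellite-cell
#' contaminant admixture cells (boosted glial markers Apoe/Mpz/Mbp) and
#' optional low-depth cells rescaled to a target number of detected genes.
#'
#' Counts for gene g in cell c are NB with mean `libsize_c * rate_gc` and
#' variance `mu + nb_dispersion * mu^2` (`nb_dispersion = 0` degenerates to
#' Poisson). `rate_gc` is the gene's baseline rate times `marker_fold_change`
#' when g is a marker of c's cluster. Baseline rates are drawn once per
#' dataset from a log-normal with mean `baseline_mean`, so library depth is
#' right-skewed and marker programs act multiplicatively, as in plate-based
#' UMI data. Contaminant cells are admixtures: the baseline neuronal program
#' plus `contaminant_boost * baseline_mean` on the glial marker genes, which
#' have zero rate in all other cells. The default cluster proportions follow
#' the adult proprioceptor dataset (51, 31 and three ~28-cell groups out of
#' 166 cells).
#'
#' @param n_genes number of genes (including the three named glial markers)
#' @param cluster_sizes cells per planted cluster
#' @param marker_genes_per_cluster planted marker genes per cluster
#'   (disjoint across clusters)
#' @param marker_fold_change expression ratio of a marker in its home
#'   cluster relative to its baseline rate (>= 1)
#' @param marker_off_scale multiplier on a marker gene's baseline rate
#'   outside its home cluster (default 1: markers keep their baseline when
#'   off, the graded-marker model; small values such as 0.02 emulate the
#'   binary on/off subtype markers seen in adult proprioceptors)
#' @param baseline_mean mean expressed-gene rate (expected counts at unit
#'   depth); the default gives an expected per-cell total of ~45,000 UMIs
#'   over the default 5000-gene panel, matching the published mean depth of
#'   44,511 UMIs per neuron
#' @param nb_dispersion NB overdispersion; 0 = Poisson
#' @param libsize_lognormal_mu,libsize_lognormal_sigma log-normal parameters
#'   of the per-cell depth multiplier
#' @param n_contaminant_cells number of satellite-contaminated admixture
#'   cells appended to the design
#' @param contaminant_genes gene ids carrying the contaminant program
#' @param contaminant_boost multiple of `baseline_mean` added to each
#'   contaminant gene's rate in contaminated cells
#' @param n_lowdepth_cells number of low-depth cells appended
#' @param lowdepth_gene_target target number of detected genes for low-depth
#'   cells (must be < 2000, the QC detection threshold)
#' @param seed integer seed; generation is bit-identical for equal seeds
#' @return a `synthetic_spec` list
#' @export
synthetic_spec <- function(n_genes = 5000,
                           cluster_sizes = c(51, 31, 28, 28, 28),
                           marker_genes_per_cluster = 20,
                           marker_fold_change = 4,
                           marker_off_scale = 1,
                           baseline_mean = 9,
                           nb_dispersion = 0.3,
                           libsize_lognormal_mu = 0,
                           libsize_lognormal_sigma = 0.3,
                           n_contaminant_cells = 8,
                           contaminant_genes = c("Apoe", "Mpz", "Mbp"),
                           contaminant_boost = 100,
                           n_lowdepth_cells = 10,
                           lowdepth_gene_target = 1000,
                           seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               cluster_sizes = as.integer(cluster_sizes),
               marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
               marker_fold_change = marker_fold_change,
               marker_off_scale = marker_off_scale,
               baseline_mean = baseline_mean,
               nb_dispersion = nb_dispersion,
               libsize_lognormal_mu = libsize_lognormal_mu,
               libsize_lognormal_sigma = libsize_lognormal_sigma,
               n_contaminant_cells = as.integer(n_contaminant_cells),
               contaminant_genes = contaminant_genes,
               contaminant_boost = contaminant_boost,
               n_lowdepth_cells = as.integer(n_lowdepth_cells),
               lowdepth_gene_target = as.integer(lowdepth_gene_target),
               seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  if (length(spec$cluster_sizes) == 0 || sum(spec$cluster_sizes) < 1)
    stop("empty design: at least one cluster with one cell is required")
  if (any(spec$cluster_sizes < 0) || spec$n_genes < 1 ||
      spec$marker_genes_per_cluster < 0 || spec$n_contaminant_cells < 0 ||
      spec$n_lowdepth_cells < 0)
    stop("counts in a synthetic spec must be nonnegative")
  if (spec$marker_fold_change < 1) stop("marker_fold_change must be >= 1")
  if (spec$marker_off_scale < 0 || spec$marker_off_scale > 1)
    stop("marker_off_scale must be in [0, 1]")
  if (spec$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (spec$baseline_mean <= 0) stop("baseline_mean must be positive")
  if (spec$lowdepth_gene_target >= 2000)
    stop("lowdepth_gene_target must be < 2000")
  n_markers <- length(spec$cluster_sizes) * spec$marker_genes_per_cluster
  if (n_markers + length(spec$contaminant_genes) > spec$n_genes)
    stop("n_genes too small for the requested marker/contaminant genes")
  invisible(spec)
}

# NB sampler in mean/dispersion parameterization; dispersion 0 -> Poisson.
rnb <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

nb_zero_prob <- function(mu, dispersion) {
  if (dispersion == 0) exp(-mu) else
    (1 + dispersion * mu)^(-1 / dispersion)
}

# Gene-level draws for a spec: baseline rates and the marker map. Kept
# separate from the cell-level draws so a developmental time course can
# share one gene design (the adult stage's) across all stages.
gene_design <- function(spec) {
  k <- length(spec$cluster_sizes)
  contam <- spec$contaminant_genes
  n_other <- spec$n_genes - length(contam)
  gene_ids <- c(sprintf("G%04d", seq_len(n_other)), contam)
  withr::with_seed(spec$seed, {
    # baseline rates: log-normal around baseline_mean; glial markers are
    # absent from the neuronal program (rate 0) and only appear in
    # contaminated admixture cells
    sdlog <- 0.5
    rates <- stats::rlnorm(n_other,
                           meanlog = log(spec$baseline_mean) - sdlog^2 / 2,
                           sdlog = sdlog)
    rates <- c(rates, rep(0, length(contam)))
    names(rates) <- gene_ids
    marker_map <- list()
    if (spec$marker_genes_per_cluster > 0 && k > 0) {
      pool <- sample(n_other, k * spec$marker_genes_per_cluster)
      for (j in seq_len(k)) {
        idx <- pool[((j - 1) * spec$marker_genes_per_cluster + 1):
                      (j * spec$marker_genes_per_cluster)]
        marker_map[[paste0("C", j)]] <- gene_ids[idx]
      }
    }
  })
  list(gene_ids = gene_ids, rates = rates, marker_map = marker_map)
}

# Builds the deterministic design (rates, labels, flags) for a spec. The
# marker fold change and off-state scale may be attenuated, and the gene
# design may be borrowed from another spec (the adult stage), so that
# developmental stages share gene identities with weakened programs.
synthetic_design <- function(spec, fold = spec$marker_fold_change,
                             off_scale = spec$marker_off_scale,
                             genes_from = NULL) {
  k <- length(spec$cluster_sizes)
  n_clean <- sum(spec$cluster_sizes)
  n_extra <- spec$n_contaminant_cells + spec$n_lowdepth_cells
  n_cells <- n_clean + n_extra

  gd <- gene_design(if (is.null(genes_from)) spec else genes_from)
  gene_ids <- gd$gene_ids
  rates <- gd$rates
  marker_map <- gd$marker_map
  contam <- spec$contaminant_genes
  if (!all(contam %in% gene_ids))
    stop("contaminant gene(s) absent from the gene design: ",
         paste(setdiff(contam, gene_ids), collapse = ", "))

  withr::with_seed(spec$seed + 1L, {
    labels_clean <- rep(seq_len(k), times = spec$cluster_sizes)
    labels_extra <- if (n_extra > 0)
      sample(seq_len(k), n_extra, replace = TRUE) else integer(0)
    labels <- c(labels_clean, labels_extra)

    flagged_contaminant <- if (spec$n_contaminant_cells > 0)
      n_clean + seq_len(spec$n_contaminant_cells) else integer(0)
    flagged_lowdepth <- if (spec$n_lowdepth_cells > 0)
      n_clean + spec$n_contaminant_cells + seq_len(spec$n_lowdepth_cells) else
      integer(0)

    libsize <- stats::rlnorm(n_cells, spec$libsize_lognormal_mu,
                             spec$libsize_lognormal_sigma)
  })

  cell_ids <- sprintf("cell%04d", seq_len(n_cells))

  # rate matrix: baseline, marker boost in home cluster, contaminant program
  rate_mat <- matrix(rates, nrow = spec$n_genes, ncol = n_cells,
                     dimnames = list(gene_ids, cell_ids))
  for (j in seq_along(marker_map)) {
    home <- labels == j
    rate_mat[marker_map[[j]], home] <- rate_mat[marker_map[[j]], home] * fold
    rate_mat[marker_map[[j]], !home] <-
      rate_mat[marker_map[[j]], !home] * off_scale
  }
  if (length(flagged_contaminant) > 0)
    rate_mat[contam, flagged_contaminant] <-
      rate_mat[contam, flagged_contaminant] +
      spec$contaminant_boost * spec$baseline_mean

  list(rate_mat = rate_mat, labels = labels, libsize = libsize,
       gene_ids = gene_ids, cell_ids = cell_ids, marker_map = marker_map,
       flagged_contaminant = cell_ids[flagged_contaminant],
       flagged_lowdepth = cell_ids[flagged_lowdepth])
}

#' Simulate a UMI count matrix with planted ground truth
#'
#' @param spec a [synthetic_spec()]
#' @return list with `counts` (a [count_matrix()]) and `truth`, a
#'   `planted_truth` list holding `cell_labels` (named cluster id per cell),
#'   `marker_map` (cluster id -> marker gene ids), `flagged_lowdepth` and
#'   `flagged_contaminant` cell ids.
#' @examples
#' sim <- simulate_counts(synthetic_spec(n_genes = 300, seed = 7,
#'   cluster_sizes = c(20, 20), marker_genes_per_cluster = 5,
#'   n_contaminant_cells = 2, n_lowdepth_cells = 2,
#'   lowdepth_gene_target = 50))
#' dim(sim$counts)
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  des <- synthetic_design(spec)
  mu <- sweep(des$rate_mat, 2, des$libsize, "*")

  # low-depth cells: scale the whole mean vector so the expected number of
  # detected genes hits lowdepth_gene_target
  if (length(des$flagged_lowdepth) > 0) {
    for (cid in des$flagged_lowdepth) {
      m <- mu[, cid]
      f <- function(s) {
        sum(1 - nb_zero_prob(s * m, spec$nb_dispersion)) -
          spec$lowdepth_gene_target
      }
      s <- stats::uniroot(f, c(1e-8, 1), extendInt = "upX", tol = 1e-6)$root
      mu[, cid] <- s * m
    }
  }

  counts <- withr::with_seed(spec$seed + 2L, {
    matrix(rnb(length(mu), as.vector(mu), spec$nb_dispersion),
           nrow = nrow(mu), dimnames = dimnames(mu))
  })

  n_cells <- length(des$cell_ids)
  meta <- data.frame(stage = rep("adult", n_cells),
                     batch = rep("sim", n_cells),
                     row.names = des$cell_ids, stringsAsFactors = FALSE)
  truth <- structure(list(
    cell_labels = stats::setNames(paste0("C", des$labels), des$cell_ids),
    marker_map = des$marker_map,
    flagged_lowdepth = des$flagged_lowdepth,
    flagged_contaminant = des$flagged_contaminant), class = "planted_truth")
  list(counts = count_matrix(counts, meta), truth = truth)
}

#' Simulate a developmental time course with decaying marker co-expression
#'
#' The last spec in `specs` is the adult stage and keeps its full marker
#' fold change; each step back in time shrinks the log fold change (and the
#' log off-state attenuation) by `coexpression_decay`, so within-cluster
#' marker-marker correlation decays monotonically toward the earliest stage
#' (fold change `f` becomes `f^(decay^steps_back)`; decay 1 keeps every
#' stage identical in design, decay 0 removes all structure before the
#' adult stage). Gene identities, baseline rates and the marker map are the
#' adult design's at every stage — earlier stages express the same genes
#' with a weaker subtype program — while cells, depths and counts are drawn
#' per stage from each spec's own seed.
#'
#' @param specs ordered list of [synthetic_spec()], earliest stage first,
#'   adult last (>= 2 stages)
#' @param coexpression_decay per-step decay factor in \[0, 1\]
#' @param stage_names optional stage labels (default stage1..stageS)
#' @return named list per stage, each with `counts` and `truth` as in
#'   [simulate_counts()]
#' @export
simulate_timecourse <- function(specs, coexpression_decay,
                                stage_names = NULL) {
  if (length(specs) < 2) stop("a time course needs at least 2 stages")
  if (coexpression_decay < 0 || coexpression_decay > 1)
    stop("coexpression_decay must be in [0, 1]")
  s <- length(specs)
  if (is.null(stage_names)) stage_names <- paste0("stage", seq_len(s))
  out <- vector("list", s)
  names(out) <- stage_names
  for (i in seq_len(s)) {
    spec <- specs[[i]]
    stopifnot(inherits(spec, "synthetic_spec"))
    decay_i <- coexpression_decay^(s - i)
    if (coexpression_decay == 0 && i < s) decay_i <- 0
    fold <- spec$marker_fold_change^decay_i
    off_scale <- spec$marker_off_scale^decay_i
    # gene identities and rates are shared across stages (the adult design);
    # only the marker program strength and the cells differ per stage
    des <- synthetic_design(spec, fold = fold, off_scale = off_scale,
                            genes_from = specs[[s]])
    mu <- sweep(des$rate_mat, 2, des$libsize, "*")
    counts <- withr::with_seed(spec$seed + 2L, {
      matrix(rnb(length(mu), as.vector(mu), spec$nb_dispersion),
             nrow = nrow(mu), dimnames = dimnames(mu))
    })
    meta <- data.frame(stage = rep(stage_names[i], length(des$cell_ids)),
                       batch = rep("sim", length(des$cell_ids)),
                       row.names = des$cell_ids, stringsAsFactors = FALSE)
    truth <- structure(list(
      cell_labels = stats::setNames(paste0("C", des$labels), des$cell_ids),
      marker_map = des$marker_map,
      flagged_lowdepth = des$flagged_lowdepth,
      flagged_contaminant = des$flagged_contaminant,
      marker_fold_change = fold), class = "planted_truth")
    out[[i]] <- list(counts = count_matrix(counts, meta), truth = truth)
  }
  out
}

#' Write planted truth as JSON
#'
#' @param truth `planted_truth`
#' @param path output JSON file
#' @return `path`, invisibly
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$cell_labels <- as.list(x$cell_labels)  # keep cell ids as JSON keys
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}

#' The default clustering benchmark design
#'
#' A 166-cell, 2000-gene design with the adult dataset's cluster proportions
#' (51/31/28/28/28), 20 four-fold markers per cluster, planted contaminant
#' and low-depth cells for the QC stage, and per-cell depth matching the
#' published mean of ~44,500 UMIs per neuron (baseline_mean 22 over a
#' 2000-gene panel). Used by the bundled analysis scripts and the
#' acceptance checks.
#'
#' @param seed integer seed
#' @return `synthetic_spec`
#' @export
benchmark_spec <- function(seed = 1L) {
  synthetic_spec(n_genes = 2000,
                 cluster_sizes = c(51, 31, 28, 28, 28),
                 marker_genes_per_cluster = 20,
                 marker_fold_change = 4,
                 baseline_mean = 22,
                 lowdepth_gene_target = 400,
                 seed = seed)
}
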