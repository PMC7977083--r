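#' Gene-gene Pearson correlation matrix
#'
#' Pairwise Pearson correlations of log(CPM + 1) (natural log; Pearson r is
#' invariant to the log base) across all cells. Zero-variance genes get
#' r = 0 against every other gene (recorded in the `zero_variance`
#' attribute) so the matrix stays well formed; the diagonal is 1.
#'
#' @param norm CPM matrix, genes x cells
#' @param genes gene ids to correlate (>= 2)
#' @return genes x genes correlation matrix with attribute `zero_variance`
#' @export
gene_correlation_matrix <- function(norm, genes) {
  if (ncol(norm) < 3) stop("need at least 3 cells")
  genes <- as.character(genes)
  if (length(genes) < 2) stop("need at least 2 genes")
  missing <- setdiff(genes, rownames(norm))
  if (length(missing) > 0) stop("genes absent from matrix: ",
                                paste(missing, collapse = ", "))
  x <- t(log(norm[genes, , drop = FALSE] + 1))
  sdv <- apply(x, 2, stats::sd)
  r <- suppressWarnings(fast_cor(x))
  zv <- sdv == 0
  r[zv, ] <- 0
  r[, zv] <- 0
  diag(r) <- 1
  attr(r, "zero_variance") <- genes[zv]
  r
}

#' Reference gene ordering from the adult correlation matrix
#'
#' Average-linkage hierarchical clustering on the distance `1 - r` of the
#' reference-stage (adult) correlation matrix; the returned order is the
#' dendrogram leaf order, with deterministic tie-breaking (lower input
#' index first, as in `stats::hclust`).
#'
#' @param adult_matrix square symmetric correlation matrix with gene
#'   dimnames
#' @return character vector of gene ids in display order
#' @export
reference_ordering <- function(adult_matrix) {
  if (nrow(adult_matrix) != ncol(adult_matrix) ||
      !isTRUE(all.equal(adult_matrix, t(adult_matrix),
                        check.attributes = FALSE, tolerance = 1e-8)))
    stop("adult_matrix must be square and symmetric")
  if (nrow(adult_matrix) == 2) return(rownames(adult_matrix))
  d <- stats::as.dist(1 - adult_matrix)
  hc <- stats::hclust(d, method = "average")
  rownames(adult_matrix)[hc$order]
}

#' Longitudinal gene-gene correlation panel
#'
#' One correlation matrix per developmental stage, computed on log(CPM + 1)
#' over all cells of that stage and displayed in the gene order given by
#' average-linkage clustering of the reference (adult) stage. The per-stage
#' summary statistic is the mean |r| over within-group gene pairs, where
#' `gene_groups` typically holds the adult marker modules; in the published
#' analysis this statistic is strongest in the adult and decays toward
#' earlier stages.
#'
#' @param datasets named list: stage label -> CPM matrix (genes x cells)
#' @param genes gene ids to analyze; genes missing from any stage are
#'   dropped everywhere with a warning
#' @param reference_stage stage label whose clustering fixes the gene order
#'   (default: last stage)
#' @param gene_groups optional named list of gene id vectors (e.g. marker
#'   modules) defining the within-group summary pairs; defaults to one
#'   group containing all analyzed genes
#' @return `correlation_panel`: list with `stages`, `matrices` (one
#'   reordered matrix per stage), `gene_order`, `reference_stage`, and
#'   `within_group_mean_abs_r` (named numeric, one per stage)
#' @export
build_panel <- function(datasets, genes, reference_stage = NULL,
                        gene_groups = NULL) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  stages <- names(datasets)
  if (is.null(reference_stage)) reference_stage <- stages[length(stages)]
  if (!reference_stage %in% stages) stop("reference stage absent: ",
                                         reference_stage)
  genes <- as.character(genes)
  present <- Reduce(intersect, lapply(datasets, rownames), genes)
  dropped <- setdiff(genes, present)
  if (length(dropped) > 0)
    warning("genes missing at one or more stages, dropped everywhere: ",
            paste(dropped, collapse = ", "))
  genes <- genes[genes %in% present]
  if (length(genes) < 2) stop("fewer than 2 genes present at every stage")

  mats <- lapply(datasets, gene_correlation_matrix, genes = genes)
  gene_order <- reference_ordering(mats[[reference_stage]])
  mats <- lapply(mats, function(m) m[gene_order, gene_order])

  if (is.null(gene_groups)) gene_groups <- list(all = genes)
  gene_groups <- lapply(gene_groups, intersect, y = genes)
  summary_stat <- vapply(mats, function(m) {
    vals <- unlist(lapply(gene_groups, function(g) {
      if (length(g) < 2) return(numeric(0))
      sub <- abs(m[g, g])
      sub[upper.tri(sub)]
    }))
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))

  structure(list(stages = stages, matrices = mats, gene_order = gene_order,
                 reference_stage = reference_stage,
                 within_group_mean_abs_r = summary_stat),
            class = "correlation_panel")
}

#' Write a correlation panel
#'
#' One TSV matrix per stage plus a JSON manifest (stages, gene order,
#' reference stage, per-stage summary statistic).
#'
#' @param panel `correlation_panel`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in panel$stages)
    utils::write.table(panel$matrices[[s]],
                       file.path(dir, paste0("correlation_", s, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  manifest <- list(stages = panel$stages,
                   reference_stage = panel$reference_stage,
                   gene_order = panel$gene_order,
                   within_group_mean_abs_r =
                     as.list(panel$within_group_mean_abs_r))
  jsonlite::write_json(manifest, file.path(dir, "panel.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
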