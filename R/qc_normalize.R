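#' Counts-per-million normalization
#'
#' Each gene's UMI count is divided by the cell's total UMI count and
#' multiplied by 1e6, so every cell with positive depth sums to one million.
#' Cells with zero total count become all-zero columns and are reported with
#' a warning rather than an error.
#'
#' @param counts a [count_matrix()]
#' @return numeric matrix of CPM values, genes x cells, same dimnames
#' @export
cpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  tot <- colSums(counts$counts)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("%d cell(s) with zero total count left as all-zero: %s",
                    sum(zero),
                    paste(counts$cell_ids[zero], collapse = ", ")))
    tot[zero] <- 1
  }
  sweep(counts$counts, 2, tot, "/") * 1e6
}

#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the number of detected genes (count > 0), the
#' total UMI count, and the CPM of the satellite/Schwann-cell contamination
#' markers, and evaluates both published filtering dialects:
#' \describe{
#'   \item{`methods`}{keep iff Mbp CPM < 10,000 and Apoe CPM < 20 (the
#'     fixed thresholds; default dialect).}
#'   \item{`main_text`}{keep iff the cell's summed raw count over the
#'     Apoe/Mpz contaminant markers is at most 10\% of the dataset mean of
#'     that sum.}
#' }
#' The gene-detection flag is `genes_detected >= min_genes` (cells under
#' 2000 detected genes are removed in the source protocol). Zero-total
#' cells always fail.
#'
#' @param counts a [count_matrix()]
#' @param contaminant_genes gene ids of the glial markers; missing names are
#'   warned about and treated as zero
#' @param min_genes gene-detection threshold (default 2000)
#' @param dialect which contamination rule the `pass_contamination` column
#'   reflects
#' @param mbp_cpm_max,apoe_cpm_max methods-dialect thresholds
#' @param main_text_frac main-text-dialect fraction of the dataset mean
#' @return `cell_qc_report`: data.frame with one row per cell (columns
#'   `cell_id`, `genes_detected`, `total_umi`, one `cpm_<gene>` column per
#'   contaminant gene, `pass_genes`, `pass_contamination`,
#'   `pass_contamination_methods`, `pass_contamination_main_text`) plus
#'   attributes `dialect` and `min_genes`.
#' @export
qc_metrics <- function(counts, contaminant_genes = c("Apoe", "Mpz", "Mbp"),
                       min_genes = 2000,
                       dialect = c("methods", "main_text"),
                       mbp_cpm_max = 10000, apoe_cpm_max = 20,
                       main_text_frac = 0.1) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  if (ncol(m) == 0) {
    rep0 <- data.frame(cell_id = character(0), genes_detected = integer(0),
                       total_umi = numeric(0), pass_genes = logical(0),
                       pass_contamination = logical(0))
    attr(rep0, "dialect") <- dialect
    class(rep0) <- c("cell_qc_report", "data.frame")
    return(rep0)
  }
  missing <- setdiff(contaminant_genes, counts$gene_ids)
  if (length(missing) > 0)
    warning("contaminant gene(s) absent, treated as zero: ",
            paste(missing, collapse = ", "))

  genes_detected <- colSums(m > 0)
  total_umi <- colSums(m)
  cpm <- suppressWarnings(cpm_normalize(counts))

  contam_cpm <- sapply(contaminant_genes, function(g) {
    if (g %in% counts$gene_ids) cpm[g, ] else rep(0, ncol(m))
  })
  if (is.null(dim(contam_cpm)))
    contam_cpm <- matrix(contam_cpm, nrow = ncol(m),
                         dimnames = list(counts$cell_ids, contaminant_genes))

  get_cpm <- function(g) if (g %in% colnames(contam_cpm)) contam_cpm[, g] else
    rep(0, ncol(m))
  pass_methods <- get_cpm("Mbp") < mbp_cpm_max & get_cpm("Apoe") < apoe_cpm_max

  # main-text rule on raw counts of the Apoe/Mpz pair
  mt_genes <- intersect(c("Apoe", "Mpz"), counts$gene_ids)
  mt_sum <- if (length(mt_genes) > 0)
    colSums(m[mt_genes, , drop = FALSE]) else rep(0, ncol(m))
  pass_main <- mt_sum <= main_text_frac * mean(mt_sum)
  if (mean(mt_sum) == 0) pass_main <- rep(TRUE, ncol(m))

  pass_genes <- genes_detected >= min_genes & total_umi > 0

  out <- data.frame(cell_id = counts$cell_ids,
                    genes_detected = as.integer(genes_detected),
                    total_umi = total_umi,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (g in contaminant_genes) out[[paste0("cpm_", g)]] <- unname(get_cpm(g))
  out$pass_genes <- unname(pass_genes)
  out$pass_contamination_methods <- unname(pass_methods)
  out$pass_contamination_main_text <- unname(pass_main)
  out$pass_contamination <- if (dialect == "methods")
    out$pass_contamination_methods else out$pass_contamination_main_text
  attr(out, "dialect") <- dialect
  attr(out, "min_genes") <- min_genes
  class(out) <- c("cell_qc_report", "data.frame")
  out
}

#' Remove cells failing quality control
#'
#' The gene-detection rule is applied first; the contamination rule (in the
#' report's dialect) is applied to the survivors, so a cell failing both is
#' reported under `lowdepth`.
#'
#' @param counts a [count_matrix()]
#' @param report a `cell_qc_report` computed on the same matrix
#' @return list with `kept` (a [count_matrix()] of surviving cells) and
#'   `removed`, a list of `lowdepth` and `contaminated` cell ids
#' @export
filter_cells <- function(counts, report) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(report, "cell_qc_report"))
  if (!identical(report$cell_id, counts$cell_ids))
    stop("report does not match the matrix's cells")
  lowdepth <- report$cell_id[!report$pass_genes]
  survivors <- report[report$pass_genes, , drop = FALSE]
  contaminated <- survivors$cell_id[!survivors$pass_contamination]
  keep <- setdiff(counts$cell_ids, c(lowdepth, contaminated))
  if (length(keep) == 0) stop("no cells survive QC")
  list(kept = subset_cells(counts, keep),
       removed = list(lowdepth = lowdepth, contaminated = contaminated))
}

#' Write a QC report as TSV
#'
#' @param report `cell_qc_report`
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
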