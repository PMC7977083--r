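#' UMI count matrix container
#'
#' A light container for an integer UMI count matrix (genes x cells) together
#' with per-cell metadata. Rows are genes, columns are cells; both carry
#' unique character identifiers.
#'
#' @param counts integer matrix, genes x cells, with unique rownames (gene
#'   ids) and colnames (cell ids). Negative entries are rejected.
#' @param cell_meta optional data.frame with one row per cell (rownames =
#'   cell ids) holding at least `stage` and `batch` columns; defaults are
#'   filled in when absent.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("cell ids must be unique")
  if (any(counts < 0)) stop("counts must be nonnegative")
  storage.mode(counts) <- "double"  # integer counts, double storage for size
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(stage = rep("unknown", ncol(counts)),
                            batch = rep("unknown", ncol(counts)),
                            row.names = colnames(counts),
                            stringsAsFactors = FALSE)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (!all(colnames(counts) %in% rownames(cell_meta)))
      stop("cell_meta must cover every cell id")
    cell_meta <- cell_meta[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 cell_ids = colnames(counts),
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total UMIs: %.0f; stages: %s\n", sum(x$counts),
              paste(unique(x$cell_meta$stage), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by cells (and optionally genes)
#'
#' @param x `count_matrix`
#' @param cells character vector of cell ids or integer/logical index
#' @param genes optional gene ids or index
#' @return `count_matrix` restricted to the requested cells/genes
#' @export
subset_cells <- function(x, cells, genes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts[, cells, drop = FALSE]
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  # already-validated source: rebuild without re-running the checks
  structure(list(counts = m, gene_ids = rownames(m),
                 cell_ids = colnames(m),
                 cell_meta = x$cell_meta[colnames(m), , drop = FALSE]),
            class = "count_matrix")
}

#' Read a UMI count matrix
#'
#' Two dialects are supported: `"mtx"` (MatrixMarket file with `genes.tsv`
#' and `cells.tsv` sidecars in the same directory; MTX coordinates are
#' 1-based per the MatrixMarket standard) and `"csv"` (dense CSV with gene
#' ids in the first column and cell ids as header).
#'
#' @param path for `"mtx"`, the `.mtx` file (sidecars are looked up next to
#'   it); for `"csv"`, the CSV file.
#' @param dialect `"mtx"` or `"csv"`
#' @return `count_matrix`
#' @export
read_counts <- function(path, dialect = c("mtx", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "mtx") {
    dirn <- dirname(path)
    gf <- file.path(dirn, "genes.tsv")
    cf <- file.path(dirn, "cells.tsv")
    if (!file.exists(gf)) stop("missing sidecar: ", gf)
    if (!file.exists(cf)) stop("missing sidecar: ", cf)
    m <- as.matrix(Matrix::readMM(path))
    genes <- utils::read.delim(gf, header = TRUE, stringsAsFactors = FALSE)
    cells <- utils::read.delim(cf, header = TRUE, stringsAsFactors = FALSE)
    if (nrow(genes) != nrow(m))
      stop("dimension mismatch between matrix and sidecar: ", gf)
    if (nrow(cells) != ncol(m))
      stop("dimension mismatch between matrix and sidecar: ", cf)
    rownames(m) <- genes$gene_id
    colnames(m) <- cells$cell_id
    meta <- cells[, setdiff(colnames(cells), "cell_id"), drop = FALSE]
    rownames(meta) <- cells$cell_id
    count_matrix(m, meta)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    count_matrix(m)
  }
}

#' Write a UMI count matrix
#'
#' Inverse of [read_counts()]; `write_counts` followed by `read_counts` is
#' lossless for integer counts and preserves gene/cell order.
#'
#' @param x `count_matrix`
#' @param path output `.mtx` or `.csv` file
#' @param dialect `"mtx"` or `"csv"`
#' @return `path`, invisibly
#' @export
write_counts <- function(x, path, dialect = c("mtx", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "count_matrix"))
  if (dialect == "mtx") {
    dirn <- dirname(path)
    if (!dir.exists(dirn)) dir.create(dirn, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(x$counts, sparse = TRUE),
                                "generalMatrix"), path)
    utils::write.table(data.frame(gene_id = x$gene_ids),
                       file.path(dirn, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(data.frame(cell_id = x$cell_ids),
                             x$cell_meta),
                       file.path(dirn, "cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
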