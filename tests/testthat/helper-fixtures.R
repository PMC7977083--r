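# Small programmatic fixtures shared across test files.

# A tiny count matrix with hand-set entries.
tiny_counts <- function(m) {
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  count_matrix(m)
}

# Counts with two planted groups differing in `n_de` genes by `fold`.
# Returns list(counts, labels).
two_group_counts <- function(n_genes = 200, n_per_group = 20, n_de = 10,
                             fold = 4, base = 20, seed = 1) {
  withr::with_seed(seed, {
    mu <- matrix(base, n_genes, 2 * n_per_group)
    mu[seq_len(n_de), seq_len(n_per_group)] <- base * fold
    m <- matrix(rpois(length(mu), mu), nrow = n_genes)
  })
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- sprintf("c%03d", seq_len(2 * n_per_group))
  labels <- stats::setNames(rep(c(1L, 2L), each = n_per_group),
                            colnames(m))
  list(counts = count_matrix(m), labels = labels)
}

# A CPM matrix with two planted co-expression blocks over a noise floor.
# Block genes follow a shared cell profile plus small independent noise.
blocky_cpm <- function(block_sizes = c(10, 10), n_noise = 20, n_cells = 60,
                       noise_sd = 0.15, seed = 1) {
  withr::with_seed(seed, {
    profiles <- matrix(rnorm(length(block_sizes) * n_cells),
                       nrow = length(block_sizes))
    rows <- list()
    for (b in seq_along(block_sizes)) {
      for (i in seq_len(block_sizes[b])) {
        rows[[length(rows) + 1]] <- profiles[b, ] +
          rnorm(n_cells, sd = noise_sd)
      }
    }
    for (i in seq_len(n_noise)) {
      rows[[length(rows) + 1]] <- rnorm(n_cells)
    }
    x <- do.call(rbind, rows)
  })
  # shift to positive "CPM" scale; correlations are shift-invariant but
  # log10(CPM + 1) is applied downstream, so spread values well above 1
  cpm <- 10^(x + 3)
  rownames(cpm) <- c(sprintf("blk%d_g%02d",
                             rep(seq_along(block_sizes), block_sizes),
                             unlist(lapply(block_sizes, seq_len))),
                     sprintf("noise%02d", seq_len(n_noise)))
  colnames(cpm) <- sprintf("c%03d", seq_len(n_cells))
  cpm
}

block_gene_ids <- function(cpm, block) {
  grep(sprintf("^blk%d_", block), rownames(cpm), value = TRUE)
}

# Adjusted Rand index oracle for small tests (mclust is available in the
# test environment; alias kept in one place).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
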