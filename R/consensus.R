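#' Bootstrapped co-clustering
#'
#' Repeats the full iterative clustering `n_iter` times on random subsets
#' of `floor(frac * n)` cells drawn without replacement (run `i` uses seed
#' `seed + i`), and records, for every cell pair, the proportion of runs in
#' which both cells were sampled and assigned to the same cluster among
#' the runs sampling both.
#'
#' @param counts a QC-filtered [count_matrix()]
#' @param config a [pipeline_config()] (clustering/DE settings for each run)
#' @param n_iter number of bootstrap runs (default 100)
#' @param frac subsampling fraction (default 0.8)
#' @param seed master seed for the run-specific seeds
#' @return `cocluster_matrix`: list with `coclust` (cells x cells
#'   proportions, NA where a pair was never co-sampled, diagonal 1 for any
#'   sampled cell), `cosample_counts`, `n_iter`, `subsample_frac`, and
#'   `runs` (list of named label vectors, one per run)
#' @export
bootstrap_coclustering <- function(counts, config = pipeline_config(),
                                   n_iter = 100, frac = 0.8,
                                   seed = config$seed) {
  stopifnot(inherits(counts, "count_matrix"))
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  n <- ncol(counts$counts)
  n_sub <- floor(frac * n)
  if (n_sub < 2 * config$clustering$min_cluster_size)
    stop("frac too small: runs would have fewer than 2 x min_cluster_size",
         " cells")
  cells <- counts$cell_ids
  same <- matrix(0L, n, n, dimnames = list(cells, cells))
  both <- matrix(0L, n, n, dimnames = list(cells, cells))
  runs <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    run_seed <- as.integer(seed + i)
    idx <- withr::with_seed(run_seed, sort(sample(n, n_sub)))
    sub <- subset_cells(counts, cells[idx])
    run_config <- config
    run_config$seed <- run_seed
    asg <- iter_cluster(sub, run_config)
    runs[[i]] <- asg$labels
    both[idx, idx] <- both[idx, idx] + 1L
    for (cl in unique(asg$labels)) {
      member_idx <- idx[asg$labels[cells[idx]] == cl]
      same[member_idx, member_idx] <- same[member_idx, member_idx] + 1L
    }
  }
  coclust <- same / both
  coclust[both == 0] <- NA
  structure(list(coclust = coclust, cosample_counts = both,
                 n_iter = n_iter, subsample_frac = frac, runs = runs),
            class = "cocluster_matrix")
}

#' Rebuild a co-clustering matrix from archived run labels
#'
#' Direct recomputation over the per-run label archive; used as the
#' reference path for the accumulating implementation in
#' [bootstrap_coclustering()].
#'
#' @param runs list of named label vectors (cells sampled in that run)
#' @param cells all cell ids
#' @return list with `coclust` and `cosample_counts`
#' @export
coclustering_from_runs <- function(runs, cells) {
  n <- length(cells)
  same <- matrix(0L, n, n, dimnames = list(cells, cells))
  both <- matrix(0L, n, n, dimnames = list(cells, cells))
  for (labels in runs) {
    ids <- names(labels)
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        both[ids[a], ids[b]] <- both[ids[a], ids[b]] + 1L
        if (labels[a] == labels[b])
          same[ids[a], ids[b]] <- same[ids[a], ids[b]] + 1L
      }
    }
  }
  coclust <- same / both
  coclust[both == 0] <- NA
  list(coclust = coclust, cosample_counts = both)
}

#' Merge reference clusters by mean co-clustering
#'
#' For each pair of reference clusters the mean of the defined co-clustering
#' entries over all cross-cluster cell pairs is computed; while the highest
#' mean exceeds `threshold` (strictly) that pair is merged and the means
#' recomputed. Pairs with no co-sampled cell pairs get mean 0 with a
#' warning.
#'
#' After merging, each cell is reassigned to the cluster whose members it
#' co-clusters with most (majority voting over the bootstrap runs,
#' excluding the cell itself), iterated synchronously until stable or
#' `reassign_iters` passes; this repairs boundary cells that a single
#' reference run placed on the wrong side of an early split. Set
#' `reassign_iters = 0` for the bare merge rule.
#'
#' @param reference a `cluster_assignment` (e.g. one [iter_cluster()] run on
#'   the full data)
#' @param coclust a `cocluster_matrix`
#' @param threshold merge above this mean co-clustering (default 0.25;
#'   a mean of exactly 0.25 is not merged)
#' @param minor_size cluster size below which the merged clusters are
#'   flagged minor (default 15)
#' @param reassign_iters maximum majority-vote refinement passes (default 3)
#' @return `cluster_assignment` after consensus merging (labels renumbered
#'   1..K by decreasing size)
#' @export
consensus_merge <- function(reference, coclust, threshold = 0.25,
                            minor_size = 15, reassign_iters = 3) {
  stopifnot(inherits(reference, "cluster_assignment"),
            inherits(coclust, "cocluster_matrix"))
  labels <- reference$labels
  if (!all(names(labels) %in% rownames(coclust$coclust)))
    stop("reference labels must cover the co-clustering matrix's cells")
  cc <- coclust$coclust

  pair_mean <- function(labels, a, b) {
    ca <- names(labels)[labels == a]
    cb <- names(labels)[labels == b]
    vals <- cc[ca, cb, drop = FALSE]
    if (all(is.na(vals))) {
      warning(sprintf("clusters %s and %s share no co-sampled cell pairs;",
                      a, b), " mean treated as 0")
      return(0)
    }
    mean(vals, na.rm = TRUE)
  }

  repeat {
    ids <- sort(unique(labels))
    if (length(ids) < 2) break
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    means <- vapply(pairs, function(p) pair_mean(labels, p[1], p[2]),
                    numeric(1))
    i <- which.max(means)
    if (means[i] <= threshold) break
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    labels[labels == b] <- a
  }

  # majority-vote refinement on the co-clustering matrix
  if (reassign_iters > 0 && length(unique(labels)) > 1) {
    cc0 <- cc
    w <- 1 - is.na(cc0)
    cc0[is.na(cc0)] <- 0
    diag(cc0) <- 0
    diag(w) <- 0
    cells <- names(labels)
    for (pass in seq_len(reassign_iters)) {
      ids <- sort(unique(labels))
      ind <- vapply(ids, function(k) as.numeric(labels == k),
                    numeric(length(labels)))
      num <- cc0[cells, cells] %*% ind
      den <- w[cells, cells] %*% ind
      means <- ifelse(den > 0, num / den, 0)
      # argmax with a stay-put tie break
      cur <- match(labels, ids)
      best <- max.col(means, ties.method = "first")
      stay <- means[cbind(seq_along(cur), cur)] >=
        means[cbind(seq_along(cur), best)]
      best[stay] <- cur[stay]
      new_labels <- stats::setNames(ids[best], cells)
      if (identical(unname(new_labels), unname(labels))) break
      labels <- new_labels
    }
  }

  # renumber 1..K by decreasing size, stable on previous ids
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- stats::setNames(unname(relabel[as.character(labels)]),
                            names(labels))
  new_sizes <- table(labels)
  minor <- stats::setNames(as.vector(new_sizes) < minor_size,
                           names(new_sizes))
  structure(list(labels = labels, minor_flags = minor,
                 tree = reference$tree), class = "cluster_assignment")
}

#' Write a co-clustering matrix as TSV
#'
#' @param coclust `cocluster_matrix`
#' @param path output TSV (proportions; NA for never-co-sampled pairs)
#' @return `path`, invisibly
#' @export
write_coclustering <- function(coclust, path) {
  utils::write.table(coclust$coclust, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
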