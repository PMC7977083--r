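#' Split cells once in eigengene space
#'
#' Cells are clustered with Ward-linkage hierarchical clustering on the
#' distance `1 - Pearson r` between their eigengene vectors (Ward applied
#' directly to the correlation distance, treated as squared-Euclidean
#' compatible). The tree is cut at `k = min(k_max, floor(n /
#' min_cluster_size))` and clusters smaller than `min_cluster_size` are
#' reabsorbed into the cluster with the highest mean cell-cell correlation.
#' With fewer than `2 * min_cluster_size` cells a single cluster is
#' returned. With fewer than three eigengenes the cell-cell correlation is
#' degenerate (for two eigengenes it is exactly +/-1), so Euclidean
#' distance on the eigengene coordinates is used instead.
#'
#' @param eig eigengene matrix, modules x cells
#' @param min_cluster_size smallest cluster allowed (default 4)
#' @param k_max maximum candidate clusters per split (default 4); the
#'   downstream merge step collapses spurious splits
#' @return integer vector of candidate labels (1..k), named by cell id
#' @export
split_once <- function(eig, min_cluster_size = 4, k_max = 4) {
  n <- ncol(eig)
  cells <- colnames(eig)
  if (n < 2 * min_cluster_size)
    return(stats::setNames(rep(1L, n), cells))
  if (nrow(eig) >= 3) {
    r <- fast_cor(eig)              # cells x cells correlation
    r[is.na(r)] <- 0
    d <- stats::as.dist(1 - r)
  } else {
    d <- stats::dist(t(eig))
  }
  hc <- stats::hclust(d, method = "ward.D")
  k <- min(k_max, floor(n / min_cluster_size))
  labels <- stats::cutree(hc, k = k)

  # reabsorb clusters below the size floor into the nearest large cluster
  if (nrow(eig) >= 3) sim <- r else sim <- -as.matrix(d)
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_cluster_size]
    big <- names(sizes)[sizes >= min_cluster_size]
    if (length(small) == 0 || length(big) == 0) break
    for (s in small) {
      members <- which(labels == as.integer(s))
      for (m in members) {
        best <- big[which.max(vapply(big, function(b) {
          mean(sim[m, labels == as.integer(b), drop = TRUE])
        }, numeric(1)))]
        labels[m] <- as.integer(best)
      }
    }
    if (length(small) == 0) break
  }
  if (length(unique(labels)) == 1)
    return(stats::setNames(rep(1L, n), cells))
  stats::setNames(match(labels, sort(unique(labels))), cells)
}

#' Differential-expression score for a cluster pair
#'
#' Runs the moderated-t differential expression test ([moderated_de()])
#' between the two clusters and sums, over genes called DE (BH-adjusted p <
#' `fdr` and |log2 fold change| >= `lfc`), the raw `-log10 p` capped at
#' `cap` per gene. Large scores mean the pair is transcriptionally
#' distinct; pairs scoring below the merge threshold (100 in the published
#' procedure) are collapsed.
#'
#' @param counts a [count_matrix()]
#' @param labels named cluster labels covering the matrix's cells
#' @param pair length-2 vector of cluster ids
#' @param d0 prior degrees of freedom of the moderated t (default 4)
#' @param fdr adjusted-p cutoff for calling a gene DE (default 0.05)
#' @param lfc absolute log2 fold-change cutoff (default 1)
#' @param cap per-gene cap on -log10 p (default 20)
#' @param norm optional precomputed CPM matrix of the same cells
#' @return nonnegative score (attribute `n_de`: number of DE genes)
#' @export
pair_merge_score <- function(counts, labels, pair, d0 = 4, fdr = 0.05,
                             lfc = 1, cap = 20, norm = NULL) {
  n1 <- sum(labels == pair[1])
  n2 <- sum(labels == pair[2])
  if (n1 == 0 || n2 == 0) stop("both clusters must be nonempty")
  if (n1 < 2 || n2 < 2) {
    warning("cluster with < 2 cells: insufficient replication, score 0")
    return(structure(0, n_de = 0L))
  }
  de <- moderated_de(counts, labels, pair, d0 = d0, norm = norm)
  sig <- de$adj_p < fdr & abs(de$log2_fold_change) >= lfc
  score <- sum(pmin(-log10(de$raw_p[sig]), cap))
  structure(score, n_de = sum(sig))
}

#' Score table for all cluster pairs
#'
#' @inheritParams pair_merge_score
#' @return data.frame with columns `cluster1`, `cluster2`, `score`, `n_de`
#' @export
merge_score_table <- function(counts, labels, d0 = 4, fdr = 0.05, lfc = 1,
                              cap = 20, norm = NULL) {
  if (is.null(norm)) norm <- suppressWarnings(cpm_normalize(counts))
  cl <- sort(unique(labels))
  pairs <- utils::combn(cl, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    s <- pair_merge_score(counts, labels, p, d0, fdr, lfc, cap, norm = norm)
    data.frame(cluster1 = p[1], cluster2 = p[2], score = as.numeric(s),
               n_de = attr(s, "n_de"))
  })
  do.call(rbind, rows)
}

#' Merge statistically indistinct clusters
#'
#' Repeatedly merges the pair with the smallest DE score while that score is
#' below `threshold`, recomputing the scores that involve the merged
#' cluster, until every remaining pair scores at or above the threshold.
#'
#' @param labels named cluster labels
#' @param scores data.frame as from [merge_score_table()] covering all
#'   current pairs
#' @param threshold merge below this summed -log10 p (default 100)
#' @param score_fun function `(labels, pair) -> score` used to recompute
#'   scores after a merge; defaults to a closure over `counts`
#' @param counts a [count_matrix()], required when `score_fun` is NULL
#' @param ... passed to [pair_merge_score()] by the default score function
#' @return named cluster labels after merging (original id of the larger
#'   member is kept for each merge)
#' @export
merge_by_score <- function(labels, scores, threshold = 100,
                           score_fun = NULL, counts = NULL, ...) {
  if (is.null(score_fun)) {
    if (is.null(counts)) stop("provide counts or a score_fun")
    score_fun <- function(lab, pair)
      as.numeric(pair_merge_score(counts, lab, pair, ...))
  }
  scores <- scores[, c("cluster1", "cluster2", "score")]
  repeat {
    if (nrow(scores) == 0) break
    i <- which.min(scores$score)
    if (scores$score[i] >= threshold) break
    a <- scores$cluster1[i]
    b <- scores$cluster2[i]
    # keep the id of the larger cluster
    if (sum(labels == b) > sum(labels == a)) { tmp <- a; a <- b; b <- tmp }
    labels[labels == b] <- a
    scores <- scores[scores$cluster1 != b & scores$cluster2 != b, ,
                     drop = FALSE]
    touch <- scores$cluster1 == a | scores$cluster2 == a
    if (any(touch)) {
      for (j in which(touch)) {
        other <- if (scores$cluster1[j] == a) scores$cluster2[j] else
          scores$cluster1[j]
        scores$score[j] <- score_fun(labels, c(a, other))
      }
    }
  }
  labels
}

#' Validate gene modules by the distinctness of their eigengene split
#'
#' Candidate co-expression modules can arise from selection alone: with few
#' cells, a search over thousands of genes will assemble sets whose sample
#' correlations look coherent, and any filter computed on the same
#' correlations inherits that selection bias. This validator asks the
#' question the clustering pipeline ultimately cares about: does the module
#' separate cells into transcriptionally distinct groups? Cells are split
#' by an exact two-means partition of the module eigengene and the split is
#' scored with the same capped summed -log10 p DE score used for cluster
#' merging ([pair_merge_score()]); modules whose score falls below the
#' merge threshold are discarded.
#'
#' @param moduleset `gene_module_set`
#' @param counts a [count_matrix()] of the cells in scope
#' @param norm CPM matrix of the same cells
#' @param threshold minimum DE score (default 100, the merge threshold)
#' @param d0,fdr,lfc,cap DE-score settings as in [pair_merge_score()]
#' @return `gene_module_set` with only the validated modules; their scores
#'   are kept in `split_scores`
#' @export
validate_modules <- function(moduleset, counts, norm, threshold = 100,
                             d0 = 4, fdr = 0.05, lfc = 1, cap = 20) {
  stopifnot(inherits(moduleset, "gene_module_set"))
  if (length(moduleset$modules) == 0) return(moduleset)
  scores <- vapply(moduleset$modules, function(mod) {
    eg <- suppressWarnings(eigengenes(norm, list(mod)))
    lab <- two_means_1d(eg[1, ])
    if (min(table(lab)) < 2) return(0)
    as.numeric(suppressWarnings(
      pair_merge_score(counts, lab, c(1L, 2L), d0 = d0, fdr = fdr,
                       lfc = lfc, cap = cap, norm = norm)))
  }, numeric(1))
  keep <- scores >= threshold
  out <- moduleset
  out$modules <- moduleset$modules[keep]
  out$split_scores <- scores[keep]
  if (!is.null(moduleset$significance_p))
    out$significance_p <- moduleset$significance_p[keep]
  out
}

# Exact 1-D two-means: the optimal split is a threshold on the sorted
# values; scan all cut points for the minimum within-group sum of squares.
# Deterministic (first minimum wins).
two_means_1d <- function(v) {
  n <- length(v)
  ord <- order(v)
  s <- v[ord]
  cs <- cumsum(s)
  tot <- cs[n]
  k <- seq_len(n - 1)
  # between-group SS for split after position k (maximize)
  between <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k) - tot^2 / n
  k_best <- which.max(between)
  lab <- integer(n)
  lab[ord] <- c(rep(1L, k_best), rep(2L, n - k_best))
  stats::setNames(lab, names(v))
}

#' Iterative cluster discovery
#'
#' The recursive procedure: within the current cell scope, select
#' high-Fano genes, detect co-expression modules, and test them against a
#' permutation null; if no module shows co-expression beyond chance the
#' scope is a terminal cluster. Otherwise cells are split in eigengene
#' space (Ward on correlation distance), statistically indistinct candidate
#' clusters are merged by the summed -log10 p DE score, and the procedure
#' recurses into each resulting cluster. Terminal clusters of fewer than 15
#' cells are flagged as minor.
#'
#' @param counts a QC-filtered [count_matrix()]
#' @param config a [pipeline_config()] (clustering and DE settings are
#'   honored; QC settings are not applied here)
#' @return `cluster_assignment`: list with `labels` (named cluster ids
#'   `1..K`, ordered by decreasing size), `minor_flags` (cluster id ->
#'   TRUE iff size < `minor_size`), and `tree`, the nested split/merge
#'   provenance record
#' @export
iter_cluster <- function(counts, config = pipeline_config()) {
  stopifnot(inherits(counts, "count_matrix"))
  cl <- config$clustering
  de <- config$de
  norm <- suppressWarnings(cpm_normalize(counts))
  counter <- new.env()
  counter$next_seed <- as.integer(config$seed %% 2147480000L)

  cluster_scope <- function(cell_ids, depth) {
    scope_seed <- counter$next_seed
    counter$next_seed <- counter$next_seed + 1L
    leaf <- function(reason) list(leaf = TRUE, cells = cell_ids,
                                  reason = reason, depth = depth)
    if (length(cell_ids) < 2 * cl$min_cluster_size)
      return(leaf("too few cells"))
    sub_norm <- norm[, cell_ids, drop = FALSE]
    genes <- tryCatch(fano_select(sub_norm, cl$n_top_genes),
                      error = function(e) character(0))
    if (length(genes) == 0) return(leaf("no expressed genes"))
    mods <- detect_modules(sub_norm, genes, power = cl$power,
                           cutheight = cl$cutheight,
                           min_module_size = cl$min_module_size,
                           coherence_factor = cl$coherence_factor,
                           method = cl$module_method,
                           use_tom = cl$use_tom)
    mods <- module_significance(mods, sub_norm, n_perm = cl$n_perm,
                                alpha = cl$alpha, seed = scope_seed,
                                max_stat_genes = cl$max_stat_genes)
    if (length(mods$modules) == 0) return(leaf("no significant modules"))
    sub_counts <- subset_cells(counts, cell_ids)
    mods <- validate_modules(mods, sub_counts, sub_norm,
                             threshold = cl$merge_threshold, d0 = de$d0,
                             fdr = de$fdr, lfc = de$lfc,
                             cap = cl$score_cap)
    if (length(mods$modules) == 0) return(leaf("no validated modules"))
    eg <- eigengenes(sub_norm, mods)
    cand <- split_once(eg, cl$min_cluster_size, cl$k_max)
    if (length(unique(cand)) == 1) return(leaf("single cluster"))
    tab <- merge_score_table(sub_counts, cand, d0 = de$d0, fdr = de$fdr,
                             lfc = de$lfc, cap = cl$score_cap,
                             norm = sub_norm)
    merged <- merge_by_score(cand, tab, threshold = cl$merge_threshold,
                             counts = sub_counts, d0 = de$d0,
                             fdr = de$fdr, lfc = de$lfc,
                             cap = cl$score_cap, norm = sub_norm)
    ids <- sort(unique(merged))
    if (length(ids) == 1) return(leaf("merged to one cluster"))
    children <- lapply(ids, function(id)
      cluster_scope(cell_ids[merged == id], depth + 1))
    list(leaf = FALSE, cells = cell_ids, depth = depth,
         n_modules = length(mods$modules),
         candidate_k = length(unique(cand)),
         merged_k = length(ids),
         children = children)
  }

  tree <- cluster_scope(counts$cell_ids, 0L)

  leaves <- list()
  collect <- function(node) {
    if (isTRUE(node$leaf)) leaves[[length(leaves) + 1]] <<- node$cells
    else for (ch in node$children) collect(ch)
  }
  collect(tree)
  leaves <- leaves[order(-vapply(leaves, length, 1L))]
  labels <- stats::setNames(rep(NA_integer_, ncol(counts$counts)),
                            counts$cell_ids)
  for (i in seq_along(leaves)) labels[leaves[[i]]] <- i
  sizes <- table(labels)
  minor <- stats::setNames(as.vector(sizes) < config$clustering$minor_size,
                           names(sizes))
  structure(list(labels = labels, minor_flags = minor, tree = tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf("cluster_assignment: %d cells in %d clusters (%d major)\n",
              length(x$labels), length(sizes), sum(!x$minor_flags)))
  print(sizes)
  invisible(x)
}

#' Write a cluster assignment as TSV (+ JSON provenance)
#'
#' @param assignment `cluster_assignment`
#' @param path output TSV; the provenance tree is written next to it as
#'   `<path>.tree.json`
#' @return `path`, invisibly
#' @export
write_assignment <- function(assignment, path) {
  df <- data.frame(cell_id = names(assignment$labels),
                   cluster = assignment$labels,
                   minor = assignment$minor_flags[
                     as.character(assignment$labels)],
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(prune_tree(assignment$tree),
                       paste0(path, ".tree.json"), auto_unbox = TRUE)
  invisible(path)
}

prune_tree <- function(node) {
  out <- node[setdiff(names(node), "children")]
  out$n_cells <- length(node$cells)
  out$cells <- NULL
  if (!isTRUE(node$leaf)) out$children <- lapply(node$children, prune_tree)
  out
}
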