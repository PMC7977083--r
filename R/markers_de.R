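#' Moderated-t differential expression between two clusters
#'
#' A self-contained empirical-Bayes two-sample test on log2(CPM + 1): the
#' gene-wise pooled variance `s^2` (d = n1 + n2 - 2 df) is shrunk toward a
#' prior `s0^2` (the median gene variance) with `d0` prior degrees of
#' freedom, `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`, and the moderated t
#' is referred to a t distribution with `d0 + d` df. `d0 = 0` recovers the
#' ordinary pooled t; large `d0` pools all genes to the prior variance.
#' P values are BH-adjusted within the pair. The log2 fold change is the
#' difference of mean log2(CPM + 1) (first cluster minus second).
#'
#' @param counts a [count_matrix()]
#' @param labels named cluster labels covering the matrix's cells
#' @param pair length-2 vector of cluster ids (first vs second)
#' @param d0 prior degrees of freedom (default 4)
#' @param norm optional precomputed CPM matrix for the same cells (avoids
#'   renormalizing in tight loops)
#' @return `de_result` data.frame: `gene`, `log2_fold_change`, `raw_p`,
#'   `adj_p`, `direction` (`up_in_first` / `up_in_second`)
#' @export
moderated_de <- function(counts, labels, pair, d0 = 4, norm = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(names(labels))) stop("labels must be named by cell id")
  c1 <- names(labels)[labels == pair[1]]
  c2 <- names(labels)[labels == pair[2]]
  if (length(c1) < 2 || length(c2) < 2)
    stop("each cluster needs at least 2 cells")
  cpm <- if (is.null(norm)) suppressWarnings(cpm_normalize(counts)) else norm
  x <- log2(cpm[, c(c1, c2), drop = FALSE] + 1)
  x1 <- x[, c1, drop = FALSE]
  x2 <- x[, c2, drop = FALSE]
  n1 <- length(c1); n2 <- length(c2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  s0_2 <- stats::median(s2)
  s_tilde2 <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d * s2) / (d0 + d)
  se <- sqrt(s_tilde2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se == 0, 0, (m1 - m2) / se)
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  raw_p <- 2 * stats::pt(-abs(tstat), df = df_total)
  raw_p <- pmin(raw_p, 1)
  out <- data.frame(gene = rownames(x),
                    log2_fold_change = m1 - m2,
                    raw_p = raw_p,
                    adj_p = stats::p.adjust(raw_p, "BH"),
                    direction = ifelse(m1 >= m2, "up_in_first",
                                       "up_in_second"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  attr(out, "pair") <- pair
  attr(out, "d0") <- d0
  out
}

#' Differential expression for every cluster pair
#'
#' @param counts a [count_matrix()]
#' @param labels named cluster labels
#' @param clusters cluster ids to include (default all; minor clusters are
#'   typically excluded upstream)
#' @param d0 prior degrees of freedom
#' @return named list of `de_result`, one per pair (`"a_vs_b"`)
#' @export
all_pairs_de <- function(counts, labels, clusters = NULL, d0 = 4) {
  if (is.null(clusters)) clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  pairs <- utils::combn(clusters, 2, simplify = FALSE)
  res <- lapply(pairs, function(p) moderated_de(counts, labels, p, d0))
  names(res) <- vapply(pairs, function(p) paste(p, collapse = "_vs_"), "")
  res
}

#' Select binary on/off subtype markers
#'
#' Candidate markers are genes significantly DE (adjusted p < `fdr`,
#' |log2 fold change| >= `lfc`) in at least `min_pairs` cluster pairs and
#' with binary on/off expression: detected (CPM > 0) in at least `tau_on`
#' of the cells of one or more clusters (`clusters_on`) and in at most
#' `tau_off` of the cells of one or more others (`clusters_off`). Markers
#' are ranked by the number of significant pairs, then maximum |log2 FC|.
#'
#' @param de named list from [all_pairs_de()]
#' @param norm CPM matrix, genes x cells
#' @param labels named cluster labels
#' @param tau_on minimum detected fraction for an "on" cluster (default 0.7)
#' @param tau_off maximum detected fraction for an "off" cluster (default
#'   0.2)
#' @param fdr,lfc DE significance thresholds (defaults 0.05, 1)
#' @param min_pairs minimum number of significant pairs (default 2)
#' @return `marker_table` data.frame: `gene`, `clusters_on`, `clusters_off`
#'   (comma-separated), `n_pairs_significant`, `max_abs_lfc`, `max_cpm`
#' @export
select_markers <- function(de, norm, labels, tau_on = 0.7, tau_off = 0.2,
                           fdr = 0.05, lfc = 1, min_pairs = 2) {
  if (length(de) < 1) stop("need DE results for at least one pair")
  clusters <- sort(unique(unlist(lapply(de, attr, "pair"))))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  genes <- de[[1]]$gene

  n_sig <- stats::setNames(integer(length(genes)), genes)
  max_lfc <- stats::setNames(numeric(length(genes)), genes)
  for (r in de) {
    sig <- r$adj_p < fdr & abs(r$log2_fold_change) >= lfc
    n_sig[r$gene[sig]] <- n_sig[r$gene[sig]] + 1L
    max_lfc <- pmax(max_lfc, abs(r$log2_fold_change)[match(names(max_lfc),
                                                           r$gene)])
  }

  # detected fraction per gene per cluster
  det <- sapply(clusters, function(cl) {
    cells <- names(labels)[labels == cl]
    rowMeans(norm[genes, cells, drop = FALSE] > 0)
  })
  colnames(det) <- as.character(clusters)

  on_list <- apply(det >= tau_on, 1, function(z) clusters[z],
                   simplify = FALSE)
  off_list <- apply(det <= tau_off, 1, function(z) clusters[z],
                    simplify = FALSE)

  keep <- n_sig >= min_pairs &
    vapply(on_list, length, 1L) >= 1 &
    vapply(off_list, length, 1L) >= 1
  out <- data.frame(gene = genes[keep],
                    clusters_on = vapply(on_list[keep], paste, "",
                                         collapse = ","),
                    clusters_off = vapply(off_list[keep], paste, "",
                                          collapse = ","),
                    n_pairs_significant = unname(n_sig[keep]),
                    max_abs_lfc = unname(max_lfc[keep]),
                    max_cpm = apply(norm[genes[keep], , drop = FALSE], 1,
                                    max),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$n_pairs_significant, -out$max_abs_lfc), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (set id, description, then member genes, tab
#'   separated)
#' @param universe gene universe; defaults to the union of all set genes
#' @param parents optional two-column data.frame (`set`, `parent`) of
#'   parent links for the elim procedure
#' @return `gene_set_collection`: list with `sets`, `parents`, `universe`
#' @export
read_gene_sets <- function(path, universe = NULL, parents = NULL) {
  sets <- if (requireNamespace("fgsea", quietly = TRUE)) {
    fgsea::gmtPathways(path)
  } else {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                    vapply(lines, `[`, "", 1))
  }
  gene_set_collection(sets, universe = universe, parents = parents)
}

#' Build a gene-set collection
#'
#' @param sets named list of gene id vectors
#' @param universe gene universe (default: union of all sets)
#' @param parents optional data.frame with columns `set`, `parent`; the
#'   parent graph must be acyclic
#' @return `gene_set_collection`
#' @export
gene_set_collection <- function(sets, universe = NULL, parents = NULL) {
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  sets <- lapply(sets, intersect, y = universe)
  if (!is.null(parents)) {
    parents <- as.data.frame(parents)
    stopifnot(all(c("set", "parent") %in% colnames(parents)))
    topo_order_sets(names(sets), parents)  # errors on cycles
  }
  structure(list(sets = sets, parents = parents, universe = universe),
            class = "gene_set_collection")
}

# Reverse-topological order (children before parents) of the set DAG.
topo_order_sets <- function(ids, parents) {
  kids <- split(parents$parent, parents$set)    # set -> its parents
  order <- character(0)
  mark <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  visit <- function(v) {
    if (mark[v] == 1L) stop("cyclic parent graph")
    if (mark[v] == 2L) return(invisible())
    mark[v] <<- 1L
    for (p in kids[[v]]) if (p %in% ids) visit(p)
    mark[v] <<- 2L
    order <<- c(order, v)
  }
  for (v in ids) visit(v)
  # DFS appends every ancestor before its descendants; reversing yields the
  # children-before-parents order the elim pass needs
  rev(order)
}

hyper_p <- function(overlap, set_size, universe_size, study_size) {
  stats::phyper(overlap - 1, set_size, universe_size - set_size, study_size,
                lower.tail = FALSE)
}

#' Classic Fisher gene-set enrichment
#'
#' One-sided hypergeometric test of study-set overlap for every gene set,
#' BH-adjusted across sets. A set passes the reporting filters iff its
#' overlap is at least `min_overlap` genes and both adjusted p values
#' (classic and elim; identical here) are below `p_cutoff`.
#'
#' @param study gene id vector (must be within the collection's universe)
#' @param sets a [gene_set_collection()]
#' @param min_overlap minimum overlapping genes (default 5)
#' @param p_cutoff adjusted-p reporting cutoff (default 0.01)
#' @return `enrichment_result` data.frame: `set`, `set_size`, `overlap`,
#'   `p_classic`, `p_elim`, `adj_p_classic`, `adj_p_elim`, `passes_filters`
#' @export
enrich_classic <- function(study, sets, min_overlap = 5, p_cutoff = 0.01) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (length(sets$universe) == 0) stop("empty universe")
  extra <- setdiff(study, sets$universe)
  if (length(extra) > 0)
    stop("study genes outside the universe: ", paste(extra, collapse = ", "))
  n_univ <- length(sets$universe)
  n_study <- length(study)
  rows <- lapply(names(sets$sets), function(id) {
    gs <- sets$sets[[id]]
    ov <- length(intersect(study, gs))
    data.frame(set = id, set_size = length(gs), overlap = ov,
               p_classic = hyper_p(ov, length(gs), n_univ, n_study),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_elim <- out$p_classic
  out$adj_p_classic <- stats::p.adjust(out$p_classic, "BH")
  out$adj_p_elim <- out$adj_p_classic
  out$passes_filters <- out$overlap >= min_overlap &
    out$adj_p_classic < p_cutoff & out$adj_p_elim < p_cutoff
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Topology-aware (elim) Fisher enrichment
#'
#' Processes sets children-before-parents along the acyclic parent graph.
#' Each set is tested with its current annotation; when a set's raw elim p
#' falls below `sig_cutoff`, its currently annotated study genes are
#' removed from the annotation of all its ancestors before those are
#' tested, so enrichment near the leaves is not recounted at general
#' ancestor terms. Sets annotating fewer than `node_size` genes are
#' skipped. A flat collection (no parent links) degenerates to
#' [enrich_classic()].
#'
#' @param study gene id vector within the universe
#' @param sets a [gene_set_collection()]
#' @param sig_cutoff raw elim p below which a set's study genes are
#'   eliminated from its ancestors (default 0.01)
#' @param node_size minimum annotated genes for a set to be tested
#'   (default 5)
#' @param min_overlap,p_cutoff reporting filters as in [enrich_classic()]
#' @return `enrichment_result` data.frame (skipped sets get NA p values and
#'   fail the filters)
#' @export
enrich_elim <- function(study, sets, sig_cutoff = 0.01, node_size = 5,
                        min_overlap = 5, p_cutoff = 0.01) {
  stopifnot(inherits(sets, "gene_set_collection"))
  classic <- enrich_classic(study, sets, min_overlap, p_cutoff)
  if (is.null(sets$parents) || nrow(sets$parents) == 0) {
    classic$passes_filters <- classic$passes_filters &
      classic$set_size >= node_size
    return(classic)
  }
  ids <- names(sets$sets)
  ord <- topo_order_sets(ids, sets$parents)
  ancestors <- ancestor_map(ids, sets$parents)
  annot <- sets$sets
  n_univ <- length(sets$universe)
  n_study <- length(study)
  p_elim <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (id in ord) {
    gs <- annot[[id]]
    if (length(gs) < node_size) next
    ov_genes <- intersect(study, gs)
    p_elim[id] <- hyper_p(length(ov_genes), length(gs), n_univ, n_study)
    if (!is.na(p_elim[id]) && p_elim[id] < sig_cutoff &&
        length(ov_genes) > 0) {
      for (anc in ancestors[[id]])
        annot[[anc]] <- setdiff(annot[[anc]], ov_genes)
    }
  }
  out <- classic
  out$p_elim <- unname(p_elim[out$set])
  tested <- !is.na(out$p_elim)
  out$adj_p_elim <- NA_real_
  out$adj_p_elim[tested] <- stats::p.adjust(out$p_elim[tested], "BH")
  out$passes_filters <- !is.na(out$p_elim) & !is.na(out$p_classic) &
    out$overlap >= min_overlap &
    out$adj_p_classic < p_cutoff & out$adj_p_elim < p_cutoff
  out
}

# set id -> all ancestors (transitive closure of parent links)
ancestor_map <- function(ids, parents) {
  direct <- split(parents$parent, parents$set)
  res <- stats::setNames(vector("list", length(ids)), ids)
  get_anc <- function(v) {
    if (!is.null(res[[v]])) return(res[[v]])
    ps <- intersect(direct[[v]], ids)
    anc <- ps
    for (p in ps) anc <- union(anc, get_anc(p))
    res[[v]] <<- anc
    anc
  }
  for (v in ids) res[[v]] <- get_anc(v)
  res
}
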