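# Internal: fast Pearson correlation of matrix columns via BLAS crossprod.
# Zero-variance columns yield NA correlations, as cor() would.
fast_cor <- function(x) {
  xs <- scale(x)
  r <- crossprod(xs) / (nrow(x) - 1)
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

log10_cpm <- function(cpm) log10(cpm + 1)

# column standard deviations without apply()
matrixsd_cols <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
}

#' Select high-variance genes by Fano factor
#'
#' Ranks genes by the Fano factor (sample variance over mean, denominator
#' n - 1) of their CPM values and returns the top `k`. Genes with zero mean
#' are excluded; ties are broken by gene id order.
#'
#' @param norm CPM matrix, genes x cells (rownames = gene ids)
#' @param k number of genes to keep (default 6000, the published choice)
#' @return character vector of gene ids, highest Fano first
#' @export
fano_select <- function(norm, k = 6000) {
  mu <- rowMeans(norm)
  eligible <- mu > 0
  if (!any(eligible)) stop("all-zero matrix: no gene has positive mean")
  n <- ncol(norm)
  v <- rowSums((norm - mu)^2) / (n - 1)
  fano <- v[eligible] / mu[eligible]
  ids <- rownames(norm)[eligible]
  ord <- order(-fano, ids)
  if (k > length(ids)) {
    warning(sprintf("k = %d exceeds %d eligible genes; returning all", k,
                    length(ids)))
    k <- length(ids)
  }
  ids[ord][seq_len(k)]
}

#' Detect co-expression gene modules
#'
#' WGCNA-style module detection: the adjacency between two genes is
#' `|Pearson r|^power` on log10(CPM + 1); the gene-gene distance `1 -
#' adjacency` is clustered with average-linkage hierarchical clustering and
#' the tree is cut at a single height. With `n` cells, the absolute
#' correlation of unrelated genes concentrates around `r_null = sqrt(2 /
#' (pi (n - 1)))` (about 0.06 at 166 cells), so every branch — structured
#' or not — joins the tree below a fixed cut at `cutheight = 0.995` for any
#' realistic cell count and a literal cut at that height returns the whole
#' gene set as one block (this literal behavior is available as `method =
#' "static"`). The default `"adaptive"` cut therefore places the single cut
#' at `h* = min(cutheight, 1 - coherence_factor * r_null)`, which converges
#' to `cutheight` as the cell count grows; branches of at least
#' `min_module_size` genes whose mean absolute pairwise correlation is at
#' least `coherence_factor * r_null` become modules. Detected modules must
#' still pass [module_significance()] to count as co-expression beyond
#' chance. An optional topological-overlap transform of the adjacency is
#' available but off by default.
#'
#' @param norm CPM matrix, genes x cells
#' @param genes gene ids to consider (e.g. from [fano_select()])
#' @param power soft-threshold exponent on `|r|` (default 1)
#' @param cutheight ceiling for the tree-cut height on the 1 - adjacency
#'   scale (default 0.995)
#' @param min_module_size smallest branch kept as a module (default 10)
#' @param coherence_factor multiple of the null correlation level that a
#'   module's mean |r| must reach, and that sets the adaptive cut height
#'   (default 5: well above both the sampling null and the weak
#'   technical covariation tiers, e.g. dropout-driven correlation among
#'   low-abundance genes); the resulting bar is capped at an absolute
#'   mean |r| of 0.3 so small cell scopes remain testable
#' @param method `"adaptive"` (default) or `"static"` (literal flat cut at
#'   `cutheight`, no coherence filter)
#' @param use_tom apply the topological-overlap transform before clustering
#' @return `gene_module_set`: list with `modules` (list of gene id vectors,
#'   largest first), `eigengenes` (NULL until [eigengenes()] is called),
#'   `significance_p` (NULL until [module_significance()]), and `params`
#' @export
detect_modules <- function(norm, genes, power = 1, cutheight = 0.995,
                           min_module_size = 10, coherence_factor = 5,
                           method = c("adaptive", "static"),
                           use_tom = FALSE) {
  method <- match.arg(method)
  params <- list(power = power, cutheight = cutheight,
                 min_module_size = min_module_size,
                 coherence_factor = coherence_factor,
                 method = method, use_tom = use_tom)
  empty <- structure(list(modules = list(), eigengenes = NULL,
                          significance_p = NULL, params = params),
                     class = "gene_module_set")
  genes <- intersect(genes, rownames(norm))
  if (length(genes) < min_module_size) return(empty)
  x <- t(log10_cpm(norm[genes, , drop = FALSE]))  # cells x genes
  keep <- matrixsd_cols(x) > 0
  if (any(!keep)) {
    x <- x[, keep, drop = FALSE]
    genes <- genes[keep]
  }
  if (length(genes) < min_module_size) return(empty)
  r_signed <- fast_cor(x)
  r_abs <- abs(r_signed)
  a <- r_abs^power
  if (use_tom) a <- tom_similarity(a)
  if (method == "static") {
    hc <- stats::hclust(stats::as.dist(1 - a), method = "average")
    grp <- stats::cutree(hc, h = cutheight)
    sizes <- table(grp[grp > 0])
    keep_grp <- names(sizes)[sizes >= min_module_size]
    modules <- lapply(keep_grp, function(g) genes[grp == as.integer(g)])
  } else {
    n_cells <- nrow(x)
    r_null <- sqrt(2 / (pi * (n_cells - 1)))
    # coherence bar: multiple of the sampling null, capped at an absolute
    # level so small cell scopes are not asked for near-perfect correlation
    coh_min <- min(0.3, coherence_factor * r_null)
    # permissive seeding: small branches suffice, the leave-one-out
    # refinement dissolves incoherent seeds. Seeds come from the SIGNED
    # correlation distance: the marker programs of mutually exclusive cell
    # types anti-correlate (|r| well above noise), and on the unsigned
    # scale such programs share a branch from which refinement can only
    # keep one; with sign they are maximally distant, and the eigengene
    # merge below still unifies anti-parallel programs when their joint
    # axis is one cell-type contrast
    d_seed <- 1 - sign(r_signed) * a
    hc <- stats::hclust(stats::as.dist(d_seed), method = "average")
    h_seed <- min(cutheight, 1 - (2 * r_null)^power)
    seed_min <- min(3L, min_module_size)
    grp <- stats::cutree(hc, h = h_seed)
    sizes <- table(grp)
    seed_ids <- names(sizes)[sizes >= seed_min]
    modules <- lapply(seed_ids, function(g) genes[grp == as.integer(g)])
    # eigengene-membership (kME) refinement, as in WGCNA module assignment
    modules <- refine_modules(modules, norm, genes, seed_min,
                              kme_min = coh_min, n_rounds = 2,
                              merge_cor = 0.75)
    # final filters: size and mean within-module |r| above the noise level
    modules <- Filter(function(mod) {
      idx <- match(mod, genes)
      length(mod) >= min_module_size &&
        mean_abs_offdiag(r_abs[idx, idx]) >= coh_min
    }, modules)
  }
  modules <- modules[order(-vapply(modules, length, 1L))]
  structure(list(modules = modules, eigengenes = NULL,
                 significance_p = NULL, params = params),
            class = "gene_module_set")
}

# Iterative module refinement: reassign every candidate gene to the module
# whose mean expression profile it correlates with best, keep genes whose
# best membership clears kme_min, and merge modules with near-parallel
# eigengenes (|cor| > merge_cor, WGCNA's close-module merging). Membership
# of a module's own gene is computed against the mean profile of the OTHER
# members (leave-one-out): a gene always correlates with a summary it
# contributed to, so circular membership would keep arbitrary seeds alive.
# Seeds that cannot hold seed_min members dissolve.
refine_modules <- function(modules, norm, genes, seed_min, kme_min,
                           n_rounds = 2, merge_cor = 0.75) {
  if (length(modules) == 0) return(modules)
  lx <- log10_cpm(norm[genes, , drop = FALSE])
  z <- t(scale(t(lx)))                       # gene-wise z-scores
  z[is.na(z)] <- 0
  n1 <- ncol(z) - 1                          # ||z_g||^2 for unit-sd rows
  for (round in seq_len(n_rounds)) {
    if (length(modules) == 0) return(list())
    # merge near-parallel eigengenes
    if (length(modules) > 1) {
      eg <- suppressWarnings(eigengenes(norm, modules))
      egr <- abs(suppressWarnings(stats::cor(t(eg))))
      egr[is.na(egr)] <- 0
      diag(egr) <- 0
      while (length(modules) > 1 && max(egr) > merge_cor) {
        idx <- which(egr == max(egr), arr.ind = TRUE)[1, ]
        i <- min(idx); j <- max(idx)
        modules[[i]] <- union(modules[[i]], modules[[j]])
        modules[[j]] <- NULL
        if (length(modules) < 2) break
        eg <- suppressWarnings(eigengenes(norm, modules))
        egr <- abs(suppressWarnings(stats::cor(t(eg))))
        egr[is.na(egr)] <- 0
        diag(egr) <- 0
      }
    }
    # leave-one-out membership against module mean profiles
    smat <- vapply(modules, function(mod)
      colSums(z[mod, , drop = FALSE]), numeric(ncol(z)))  # cells x modules
    dots <- z %*% smat                                    # gene x module
    s_norm2 <- colSums(smat^2)
    member <- vapply(modules, function(mod) genes %in% mod,
                     logical(length(genes)))
    kme <- dots / sqrt(n1 * rep(s_norm2, each = length(genes)))
    loo_num <- dots - n1
    loo_den <- sqrt(n1 * (rep(s_norm2, each = length(genes)) -
                            2 * dots + n1))
    kme[member] <- (loo_num / loo_den)[member]
    kme[!is.finite(kme)] <- 0
    best <- max.col(abs(kme), ties.method = "first")
    best_val <- abs(kme)[cbind(seq_along(best), best)]
    assigned <- best_val >= kme_min
    modules <- lapply(seq_along(modules), function(m)
      genes[assigned & best == m])
    modules <- Filter(function(mod) length(mod) >= seed_min, modules)
  }
  modules
}

# Unsigned topological overlap of an adjacency matrix (optional transform).
tom_similarity <- function(a) {
  diag(a) <- 0
  l <- a %*% a
  k <- colSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Permutation significance filter for gene modules
#'
#' A module's coherence statistic is the mean absolute pairwise Pearson
#' correlation of its genes on log10(CPM + 1). The null is built by
#' independently permuting each gene's values across cells `n_perm` times;
#' a module is kept iff its observed statistic exceeds the (1 - alpha)
#' quantile of its own null, and `p = (1 + #null >= obs) / (1 + n_perm)` is
#' reported. For modules larger than `max_stat_genes` the statistic
#' (observed and null alike) is computed on a fixed random subset of the
#' module's genes, keeping the test O(subset^2 x cells).
#'
#' @param moduleset `gene_module_set` from [detect_modules()]
#' @param norm CPM matrix, genes x cells
#' @param n_perm number of permutations (default 100)
#' @param alpha retention quantile (default 0.05)
#' @param seed integer seed for the permutations
#' @param max_stat_genes statistic subset cap for large modules
#' @return `gene_module_set` containing only the retained modules, with
#'   `significance_p` set (named by module rank in the input)
#' @export
module_significance <- function(moduleset, norm, n_perm = 100, alpha = 0.05,
                                seed = 1L, max_stat_genes = 200) {
  stopifnot(inherits(moduleset, "gene_module_set"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (length(moduleset$modules) == 0) {
    moduleset$significance_p <- numeric(0)
    return(moduleset)
  }
  lx <- log10_cpm(norm)
  keep <- logical(length(moduleset$modules))
  pvals <- numeric(length(moduleset$modules))
  withr::with_seed(seed, {
    for (i in seq_along(moduleset$modules)) {
      mod <- moduleset$modules[[i]]
      if (length(mod) > max_stat_genes)
        mod <- sample(mod, max_stat_genes)
      x <- t(lx[mod, , drop = FALSE])  # cells x genes
      n <- nrow(x); m <- ncol(x)
      xs <- scale(x)
      xs[is.na(xs)] <- 0
      obs <- mean_abs_offdiag(crossprod(xs) / (n - 1))
      # permuting a z-scored column leaves it z-scored, so the null only
      # needs re-indexing: one two-key order() per permutation shuffles
      # every column independently
      cols <- rep(seq_len(m), each = n)
      null <- vapply(seq_len(n_perm), function(p) {
        o <- order(cols, stats::runif(n * m))
        xp <- matrix(xs[o], n, m)
        mean_abs_offdiag(crossprod(xp) / (n - 1))
      }, numeric(1))
      pvals[i] <- (1 + sum(null >= obs)) / (1 + n_perm)
      keep[i] <- obs > stats::quantile(null, 1 - alpha, names = FALSE)
    }
  })
  structure(list(modules = moduleset$modules[keep],
                 eigengenes = NULL,
                 significance_p = stats::setNames(pvals[keep],
                                                  which(keep)),
                 params = moduleset$params),
            class = "gene_module_set")
}

mean_abs_offdiag <- function(r) {
  r <- abs(r)
  diag(r) <- NA
  mean(r, na.rm = TRUE)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' z-scored log10(CPM + 1) submatrix of its genes, i.e. the dominant
#' cell-wise expression profile. Each eigengene is scaled to unit variance
#' and sign-oriented so that its correlation with the module's mean profile
#' is nonnegative. Zero-variance genes are dropped with a warning.
#'
#' @param norm CPM matrix, genes x cells
#' @param modules list of gene id vectors (or a `gene_module_set`)
#' @return numeric matrix, modules x cells, rownames `ME1..MEk`
#' @export
eigengenes <- function(norm, modules) {
  if (inherits(modules, "gene_module_set")) modules <- modules$modules
  if (length(modules) == 0) stop("no modules to summarize")
  lx <- log10_cpm(norm)
  eg <- matrix(0, nrow = length(modules), ncol = ncol(norm),
               dimnames = list(paste0("ME", seq_along(modules)),
                               colnames(norm)))
  for (i in seq_along(modules)) {
    sub <- lx[modules[[i]], , drop = FALSE]
    sdv <- matrixsd_cols(t(sub))
    if (any(sdv == 0)) {
      warning(sprintf("module %d: dropping %d zero-variance gene(s)", i,
                      sum(sdv == 0)))
      sub <- sub[sdv > 0, , drop = FALSE]
      if (nrow(sub) == 0) next
    }
    z <- t(scale(t(sub)))               # z-score each gene across cells
    sv <- svd(t(z), nu = 1, nv = 0)     # first left singular vector of
    v <- sv$u[, 1] * sv$d[1]            # cells x genes = PC1 cell scores
    mean_profile <- colMeans(z)
    if (stats::sd(v) == 0) next
    if (suppressWarnings(stats::cor(v, mean_profile)) < 0) v <- -v
    eg[i, ] <- v / stats::sd(v)
  }
  eg
}
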