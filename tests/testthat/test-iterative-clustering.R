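test_that("well-separated eigengene blobs split cleanly", {
  withr::with_seed(1, {
    eig <- cbind(matrix(rnorm(2 * 20, mean = 3), 2, 20),
                 matrix(rnorm(2 * 20, mean = -3), 2, 20))
    eig[2, ] <- -eig[2, ] + rnorm(40, sd = 0.3)
  })
  colnames(eig) <- sprintf("c%02d", 1:40)
  truth <- rep(1:2, each = 20)
  labels <- split_once(eig, min_cluster_size = 4, k_max = 4)
  # k_max = 4 may over-split; grouping within the planted blobs must be
  # consistent: every candidate cluster stays inside one blob
  tab <- table(labels, truth)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("split_once guards small inputs and is deterministic", {
  eig <- matrix(rnorm(2 * 5), 2, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
  expect_equal(unname(split_once(eig, min_cluster_size = 4)), rep(1L, 5))

  withr::with_seed(2, big <- matrix(rnorm(3 * 30), 3, 30,
                                    dimnames = list(NULL, paste0("c", 1:30))))
  expect_identical(split_once(big), split_once(big))
})

test_that("pair merge scores reflect transcriptional distinctness", {
  tg <- two_group_counts(n_de = 10, fold = 6, n_per_group = 30, seed = 3)
  s <- pair_merge_score(tg$counts, tg$labels, c(1, 2))
  expect_gt(as.numeric(s), 100)
  expect_gte(attr(s, "n_de"), 8)

  # gene-wise identical clusters: no DE genes, score 0
  tg0 <- two_group_counts(n_de = 0, n_per_group = 20, seed = 4)
  s0 <- pair_merge_score(tg0$counts, tg0$labels, c(1, 2))
  expect_equal(as.numeric(s0), 0)

  # a cluster with < 2 cells scores 0 with a warning
  lab <- tg0$labels
  lab[lab == 2] <- 1
  lab[1] <- 2L
  expect_warning(s1 <- pair_merge_score(tg0$counts, lab, c(1, 2)),
                 "insufficient")
  expect_equal(as.numeric(s1), 0)
})

test_that("the per-gene cap bounds each DE gene's contribution", {
  # strong markers with raw p far below 1e-20: contribution capped at 20
  tg <- two_group_counts(n_genes = 100, n_de = 10, fold = 50,
                         n_per_group = 60, base = 50, seed = 5)
  de <- moderated_de(tg$counts, tg$labels, c(1, 2))
  strong <- de$raw_p < 1e-20 & abs(de$log2_fold_change) >= 1
  expect_gte(sum(strong), 10)
  s <- pair_merge_score(tg$counts, tg$labels, c(1, 2))
  expect_equal(as.numeric(s), attr(s, "n_de") * 20, tolerance = 0.2)
})

test_that("merge_by_score follows smallest-first with recomputation", {
  labels <- stats::setNames(rep(c("A", "B", "C"), each = 5),
                            sprintf("c%02d", 1:15))
  scores <- data.frame(cluster1 = c("A", "A", "B"),
                       cluster2 = c("B", "C", "C"),
                       score = c(50, 500, 500))
  # after merging A+B the recomputed (AB)-C score stays >= 100: 2 clusters
  stub <- function(lab, pair) 150
  merged <- merge_by_score(labels, scores, threshold = 100,
                           score_fun = stub)
  expect_equal(length(unique(merged)), 2)

  # boundary: score 99.9 is merged (strict < threshold)
  scores2 <- data.frame(cluster1 = "A", cluster2 = "B", score = 99.9)
  lab2 <- stats::setNames(rep(c("A", "B"), each = 5), sprintf("c%02d", 1:10))
  merged2 <- merge_by_score(lab2, scores2, threshold = 100,
                            score_fun = stub)
  expect_equal(length(unique(merged2)), 1)

  # single cluster input unchanged
  lab3 <- stats::setNames(rep("A", 5), paste0("c", 1:5))
  expect_equal(merge_by_score(lab3, scores2[0, ], score_fun = stub), lab3)
})

test_that("module validation discards selection-only modules", {
  # a module assembled from independent genes must fail the eigengene-split
  # DE validation even if its sample correlations look coherent
  withr::with_seed(6, {
    m <- matrix(rpois(300 * 40, 30), 300, 40)
  })
  rownames(m) <- sprintf("g%03d", 1:300)
  colnames(m) <- sprintf("c%02d", 1:40)
  counts <- count_matrix(m)
  norm <- cpm_normalize(counts)
  fake <- structure(list(modules = list(rownames(m)[1:15]),
                         eigengenes = NULL, significance_p = NULL,
                         params = list()), class = "gene_module_set")
  out <- validate_modules(fake, counts, norm)
  expect_length(out$modules, 0)

  # a module of true markers passes
  tg <- two_group_counts(n_de = 15, fold = 6, n_per_group = 25, seed = 7)
  norm2 <- cpm_normalize(tg$counts)
  real <- structure(list(modules = list(tg$counts$gene_ids[1:15]),
                         eigengenes = NULL, significance_p = NULL,
                         params = list()), class = "gene_module_set")
  out2 <- validate_modules(real, tg$counts, norm2)
  expect_length(out2$modules, 1)
})

test_that("homogeneous data yields a single cluster", {
  spec <- synthetic_spec(n_genes = 800, cluster_sizes = 80,
                         marker_genes_per_cluster = 0,
                         marker_fold_change = 1,
                         n_contaminant_cells = 0, n_lowdepth_cells = 0,
                         seed = 8)
  sim <- simulate_counts(spec)
  asg <- iter_cluster(sim$counts,
                      pipeline_config(clustering = list(n_top_genes = 400),
                                      seed = 8))
  expect_equal(length(unique(asg$labels)), 1)
})

test_that("iter_cluster recovers two well-separated planted clusters", {
  spec <- synthetic_spec(n_genes = 800, cluster_sizes = c(40, 40),
                         marker_genes_per_cluster = 15,
                         marker_fold_change = 6, baseline_mean = 20,
                         n_contaminant_cells = 0, n_lowdepth_cells = 0,
                         seed = 9)
  sim <- simulate_counts(spec)
  asg <- iter_cluster(sim$counts,
                      pipeline_config(clustering = list(n_top_genes = 400),
                                      seed = 9))
  truth <- sim$truth$cell_labels[names(asg$labels)]
  expect_gte(ari(asg$labels, truth), 0.95)
})

test_that("small terminal clusters are flagged minor", {
  spec <- synthetic_spec(n_genes = 800, cluster_sizes = c(40, 12),
                         marker_genes_per_cluster = 15,
                         marker_fold_change = 8, baseline_mean = 20,
                         n_contaminant_cells = 0, n_lowdepth_cells = 0,
                         seed = 10)
  sim <- simulate_counts(spec)
  asg <- iter_cluster(sim$counts,
                      pipeline_config(clustering = list(n_top_genes = 400),
                                      seed = 10))
  sizes <- table(asg$labels)
  expect_equal(unname(asg$minor_flags[names(sizes)]),
               unname(as.vector(sizes) < 15))
  expect_true(any(asg$minor_flags))
})

test_that("the full recursion is deterministic given config and seed", {
  spec <- synthetic_spec(n_genes = 600, cluster_sizes = c(30, 30),
                         marker_genes_per_cluster = 10,
                         marker_fold_change = 5,
                         n_contaminant_cells = 0, n_lowdepth_cells = 0,
                         seed = 11)
  sim <- simulate_counts(spec)
  cfg <- pipeline_config(clustering = list(n_top_genes = 300), seed = 11)
  a <- iter_cluster(sim$counts, cfg)
  b <- iter_cluster(sim$counts, cfg)
  expect_identical(a$labels, b$labels)
})
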