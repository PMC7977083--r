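# Build a cocluster_matrix object directly from given matrices.
fake_coclust <- function(coclust, cosample = NULL) {
  if (is.null(cosample))
    cosample <- matrix(10L, nrow(coclust), ncol(coclust),
                       dimnames = dimnames(coclust))
  structure(list(coclust = coclust, cosample_counts = cosample,
                 n_iter = 10, subsample_frac = 0.8, runs = list()),
            class = "cocluster_matrix")
}

fake_assignment <- function(labels, minor_size = 15) {
  sizes <- table(labels)
  structure(list(labels = labels,
                 minor_flags = stats::setNames(
                   as.vector(sizes) < minor_size, names(sizes)),
                 tree = NULL), class = "cluster_assignment")
}

test_that("co-clustering proportions equal same-cluster over co-sampled", {
  # a pair co-sampled in 50 runs, same cluster in 20 -> 0.4
  cells <- c("a", "b")
  same <- matrix(c(50, 20, 20, 50), 2, dimnames = list(cells, cells))
  both <- matrix(50, 2, 2, dimnames = list(cells, cells))
  expect_equal((same / both)["a", "b"], 0.4)

  # through the real accumulator: archived labels vs brute force
  spec <- synthetic_spec(n_genes = 400, cluster_sizes = c(15, 15),
                         marker_genes_per_cluster = 8,
                         marker_fold_change = 6,
                         n_contaminant_cells = 0, n_lowdepth_cells = 0,
                         seed = 21)
  sim <- simulate_counts(spec)
  cfg <- pipeline_config(clustering = list(n_top_genes = 200), seed = 21)
  bc <- bootstrap_coclustering(sim$counts, cfg, n_iter = 5, frac = 0.8,
                               seed = 21)
  oracle <- coclustering_from_runs(bc$runs, sim$counts$cell_ids)
  expect_identical(bc$cosample_counts, oracle$cosample_counts)
  expect_equal(bc$coclust, oracle$coclust)
})

test_that("frac 1 with deterministic clustering gives a 0/1 matrix", {
  spec <- synthetic_spec(n_genes = 400, cluster_sizes = c(20, 20),
                         marker_genes_per_cluster = 10,
                         marker_fold_change = 8, baseline_mean = 20,
                         n_contaminant_cells = 0, n_lowdepth_cells = 0,
                         seed = 22)
  sim <- simulate_counts(spec)
  cfg <- pipeline_config(clustering = list(n_top_genes = 200), seed = 22)
  bc <- bootstrap_coclustering(sim$counts, cfg, n_iter = 3, frac = 1,
                               seed = 5)
  # every run sees all cells; entries are run-averaged indicators
  expect_true(all(bc$cosample_counts == 3))
  expect_true(all(bc$coclust %in% c(0, 1)))
  expect_true(all(diag(bc$coclust) == 1))
})

test_that("too-small subsamples are rejected", {
  spec <- synthetic_spec(n_genes = 100, cluster_sizes = 9,
                         marker_genes_per_cluster = 0,
                         n_contaminant_cells = 0, n_lowdepth_cells = 0,
                         seed = 23)
  sim <- simulate_counts(spec)
  expect_error(bootstrap_coclustering(sim$counts, pipeline_config(),
                                      n_iter = 2, frac = 0.5),
               "frac too small")
  expect_error(bootstrap_coclustering(sim$counts, pipeline_config(),
                                      n_iter = 2, frac = 0),
               "frac")
})

test_that("consensus merging respects the strict > threshold rule", {
  cells <- sprintf("c%02d", 1:20)
  lab <- stats::setNames(rep(c(1L, 2L), each = 10), cells)
  base <- matrix(0, 20, 20, dimnames = list(cells, cells))
  base[1:10, 1:10] <- 1
  base[11:20, 11:20] <- 1

  # cross-cluster mean 0.3 -> merged
  cc <- base
  cc[1:10, 11:20] <- 0.3
  cc[11:20, 1:10] <- 0.3
  merged <- consensus_merge(fake_assignment(lab), fake_coclust(cc),
                            threshold = 0.25)
  expect_equal(length(unique(merged$labels)), 1)

  # cross-cluster mean exactly 0.25 -> NOT merged
  cc25 <- base
  cc25[1:10, 11:20] <- 0.25
  cc25[11:20, 1:10] <- 0.25
  kept <- consensus_merge(fake_assignment(lab), fake_coclust(cc25),
                          threshold = 0.25)
  expect_equal(length(unique(kept$labels)), 2)

  # all cross-cluster means 0 -> unchanged partition
  same <- consensus_merge(fake_assignment(lab), fake_coclust(base),
                          threshold = 0.25)
  expect_equal(ari(same$labels, lab), 1)
})

test_that("never-co-sampled cluster pairs count as mean 0 with a warning", {
  cells <- sprintf("c%02d", 1:8)
  lab <- stats::setNames(rep(c(1L, 2L), each = 4), cells)
  cc <- matrix(NA_real_, 8, 8, dimnames = list(cells, cells))
  cc[1:4, 1:4] <- 1
  cc[5:8, 5:8] <- 1
  cos <- matrix(0L, 8, 8, dimnames = list(cells, cells))
  cos[1:4, 1:4] <- 5L
  cos[5:8, 5:8] <- 5L
  expect_warning(out <- consensus_merge(fake_assignment(lab),
                                        fake_coclust(cc, cos)),
                 "no co-sampled")
  expect_equal(length(unique(out$labels)), 2)
})

test_that("consensus cluster count is monotone in the threshold", {
  cells <- sprintf("c%02d", 1:30)
  lab <- stats::setNames(rep(1:3, each = 10), cells)
  cc <- matrix(0.05, 30, 30, dimnames = list(cells, cells))
  cc[1:10, 1:10] <- 1
  cc[11:20, 11:20] <- 1
  cc[21:30, 21:30] <- 1
  cc[1:10, 11:20] <- cc[11:20, 1:10] <- 0.4
  cc[11:20, 21:30] <- cc[21:30, 11:20] <- 0.2
  counts <- vapply(c(0.1, 0.25, 0.5), function(th) {
    out <- consensus_merge(fake_assignment(lab), fake_coclust(cc),
                           threshold = th, reassign_iters = 0)
    length(unique(out$labels))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("majority-vote refinement repairs misassigned boundary cells", {
  cells <- sprintf("c%02d", 1:20)
  lab <- stats::setNames(rep(c(1L, 2L), each = 10), cells)
  # cell c10 is labeled 1 but co-clusters with cluster 2
  cc <- matrix(0, 20, 20, dimnames = list(cells, cells))
  cc[1:9, 1:9] <- 0.9
  cc[10:20, 10:20] <- 0.9
  diag(cc) <- 1
  out <- consensus_merge(fake_assignment(lab), fake_coclust(cc))
  expect_equal(unname(out$labels["c10"]), unname(out$labels["c11"]))
  expect_equal(length(unique(out$labels)), 2)
})
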