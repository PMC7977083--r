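test_that("generation is bit-identical under a fixed seed", {
  spec <- synthetic_spec(n_genes = 300, cluster_sizes = c(15, 15),
                         marker_genes_per_cluster = 5,
                         n_contaminant_cells = 2, n_lowdepth_cells = 2,
                         lowdepth_gene_target = 60, seed = 11)
  a <- simulate_counts(spec)
  b <- simulate_counts(spec)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_counts(synthetic_spec(n_genes = 300,
                                      cluster_sizes = c(15, 15),
                                      marker_genes_per_cluster = 5,
                                      n_contaminant_cells = 2,
                                      n_lowdepth_cells = 2,
                                      lowdepth_gene_target = 60,
                                      seed = 12))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("planted cluster sizes follow the requested proportions", {
  spec <- synthetic_spec(n_genes = 500, cluster_sizes = c(51, 31, 84),
                         marker_genes_per_cluster = 5,
                         n_contaminant_cells = 0, n_lowdepth_cells = 0,
                         seed = 2)
  sim <- simulate_counts(spec)
  expect_equal(ncol(sim$counts$counts), 166)
  expect_equal(as.vector(table(sim$truth$cell_labels)[c("C1", "C2", "C3")]),
               c(51, 31, 84))
  # marker sets disjoint, labels cover all cells
  expect_equal(anyDuplicated(unlist(sim$truth$marker_map)), 0)
  expect_setequal(names(sim$truth$cell_labels), sim$counts$cell_ids)
})

test_that("dispersion 0 with flat depth yields Poisson Fano factors", {
  spec <- synthetic_spec(n_genes = 400, cluster_sizes = 500,
                         marker_genes_per_cluster = 0,
                         marker_fold_change = 1, nb_dispersion = 0,
                         libsize_lognormal_sigma = 0,
                         n_contaminant_cells = 0, n_lowdepth_cells = 0,
                         seed = 3)
  sim <- simulate_counts(spec)
  m <- sim$counts$counts
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  fano <- (v / mu)[mu > 0]
  expect_gt(mean(fano), 0.9)
  expect_lt(mean(fano), 1.1)
})

test_that("per-cluster marker means converge to the planted rates", {
  spec <- synthetic_spec(n_genes = 300, cluster_sizes = c(800, 800),
                         marker_genes_per_cluster = 10,
                         marker_fold_change = 4, nb_dispersion = 0.1,
                         libsize_lognormal_sigma = 0,
                         n_contaminant_cells = 0, n_lowdepth_cells = 0,
                         seed = 4)
  sim <- simulate_counts(spec)
  m <- sim$counts$counts
  labels <- sim$truth$cell_labels
  rates <- modclust:::gene_design(spec)$rates
  for (cl in c("C1", "C2")) {
    markers <- sim$truth$marker_map[[cl]]
    home <- names(labels)[labels == cl]
    away <- names(labels)[labels != cl]
    # empirical means converge to the planted rates: fold x rate at home,
    # baseline rate elsewhere
    err_home <- rowMeans(m[markers, home]) / (4 * rates[markers]) - 1
    err_away <- rowMeans(m[markers, away]) / rates[markers] - 1
    expect_true(all(abs(err_home) < 0.05))
    expect_true(all(abs(err_away) < 0.05))
  }
})

test_that("planted low-depth cells sit below the detection threshold", {
  sim <- simulate_counts(synthetic_spec(seed = 5))
  detected <- colSums(sim$counts$counts > 0)
  low <- sim$truth$flagged_lowdepth
  expect_true(all(detected[low] < 2000))
  expect_true(all(detected[setdiff(sim$counts$cell_ids, low)] >= 2000))
})

test_that("degenerate specs are rejected", {
  expect_error(synthetic_spec(cluster_sizes = integer(0)), "empty design")
  expect_error(synthetic_spec(marker_fold_change = 0.5), "fold_change")
  expect_error(synthetic_spec(nb_dispersion = -1), "dispersion")
  expect_error(synthetic_spec(n_genes = 10, cluster_sizes = c(5, 5),
                              marker_genes_per_cluster = 10),
               "too small")
})

test_that("time course decay shapes marker fold change per stage", {
  mk_spec <- function(seed) synthetic_spec(
    n_genes = 300, cluster_sizes = c(30, 30),
    marker_genes_per_cluster = 8, marker_fold_change = 4,
    n_contaminant_cells = 0, n_lowdepth_cells = 0, seed = seed)
  specs <- lapply(1:4, mk_spec)

  tc <- simulate_timecourse(specs, coexpression_decay = 0.5)
  folds <- vapply(tc, function(s) s$truth$marker_fold_change, numeric(1))
  expect_equal(unname(folds), 4^c(0.125, 0.25, 0.5, 1))

  # decay 1: every stage keeps the full design
  tc1 <- simulate_timecourse(specs, coexpression_decay = 1)
  expect_true(all(vapply(tc1, function(s) s$truth$marker_fold_change,
                         numeric(1)) == 4))

  # decay 0: all pre-adult stages are structureless
  tc0 <- simulate_timecourse(specs, coexpression_decay = 0)
  expect_equal(unname(vapply(tc0, function(s) s$truth$marker_fold_change,
                             numeric(1))), c(1, 1, 1, 4))

  expect_error(simulate_timecourse(specs, coexpression_decay = 1.5),
               "decay")
  expect_error(simulate_timecourse(specs[1], coexpression_decay = 0.5),
               "2 stages")
})

test_that("within-module marker correlation increases toward the adult", {
  mk_spec <- function(seed) synthetic_spec(
    n_genes = 400, cluster_sizes = c(60, 60, 60),
    marker_genes_per_cluster = 10, marker_fold_change = 4,
    marker_off_scale = 0.05,
    n_contaminant_cells = 0, n_lowdepth_cells = 0, seed = seed)
  tc <- simulate_timecourse(lapply(1:4, mk_spec), coexpression_decay = 0.5)
  mean_r <- vapply(tc, function(stage) {
    norm <- suppressWarnings(cpm_normalize(stage$counts))
    lx <- log(norm + 1)
    vals <- unlist(lapply(stage$truth$marker_map, function(g) {
      r <- cor(t(lx[g, ]))
      r[upper.tri(r)]
    }))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})
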