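test_that("Fano factors follow the variance/mean definition", {
  norm <- rbind(constant = rep(5, 4),
                variable = c(0, 4, 0, 4),
                zero = rep(0, 4))
  colnames(norm) <- paste0("c", 1:4)
  # gene with CPM [0, 4] over 2 cells: mean 2, sample variance 8, Fano 4
  norm2 <- rbind(g1 = c(0, 4), g2 = c(1, 1))
  colnames(norm2) <- c("c1", "c2")
  sel <- fano_select(norm2, k = 2)
  expect_equal(sel[1], "g1")
  v <- var(c(0, 4)); m <- mean(c(0, 4))
  expect_equal(v / m, 4)

  # constant genes score zero and rank after any variable gene
  sel2 <- fano_select(norm, k = 2)
  expect_equal(sel2[1], "variable")
  expect_false("zero" %in% suppressWarnings(fano_select(norm, k = 3)))
  expect_warning(all3 <- fano_select(norm, k = 10), "exceeds")
  expect_length(all3, 2)
  expect_error(fano_select(matrix(0, 2, 2,
                                  dimnames = list(c("a", "b"), c("x", "y")))),
               "all-zero")
})

test_that("planted correlation blocks are recovered as modules", {
  cpm <- blocky_cpm(block_sizes = c(10, 10), n_noise = 20, n_cells = 60,
                    seed = 2)
  mods <- detect_modules(cpm, rownames(cpm), min_module_size = 5)
  expect_length(mods$modules, 2)
  found <- lapply(mods$modules, sort)
  expect_setequal(found, list(sort(block_gene_ids(cpm, 1)),
                              sort(block_gene_ids(cpm, 2))))
})

test_that("a duplicated gene pair forms a module at min size 2", {
  withr::with_seed(3, {
    base <- rnorm(30)
    cpm <- rbind(dupA = 10^(base + 3), dupB = 10^(base + 3),
                 matrix(10^(rnorm(30 * 8) + 3), nrow = 8,
                        dimnames = list(sprintf("n%d", 1:8), NULL)))
  })
  colnames(cpm) <- sprintf("c%02d", 1:30)
  mods <- detect_modules(cpm, rownames(cpm), min_module_size = 2)
  has_pair <- any(vapply(mods$modules, function(m)
    all(c("dupA", "dupB") %in% m), logical(1)))
  expect_true(has_pair)
})

test_that("module detection is invariant to gene input order", {
  cpm <- blocky_cpm(block_sizes = c(8, 8), n_noise = 15, n_cells = 50,
                    seed = 4)
  mods1 <- detect_modules(cpm, rownames(cpm), min_module_size = 5)
  perm <- withr::with_seed(5, sample(rownames(cpm)))
  mods2 <- detect_modules(cpm, perm, min_module_size = 5)
  norm_mods <- function(ms) sort(vapply(ms$modules, function(m)
    paste(sort(m), collapse = ","), ""))
  expect_equal(norm_mods(mods1), norm_mods(mods2))
})

test_that("permutation test retains planted blocks and reports exact p", {
  cpm <- blocky_cpm(block_sizes = c(10), n_noise = 10, n_cells = 50,
                    seed = 6)
  mods <- detect_modules(cpm, rownames(cpm), min_module_size = 5)
  sig <- module_significance(mods, cpm, n_perm = 100, seed = 9)
  expect_gte(length(sig$modules), 1)
  expect_equal(unname(sig$significance_p[1]), 1 / 101)
})

test_that("a pre-specified module of independent genes is rejected", {
  rejected <- 0
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    withr::with_seed(100 + s,
      cpm <- matrix(10^(rnorm(15 * 40) + 3), nrow = 15,
                    dimnames = list(sprintf("g%02d", 1:15),
                                    sprintf("c%02d", 1:40))))
    ms <- structure(list(modules = list(rownames(cpm)), eigengenes = NULL,
                         significance_p = NULL, params = list()),
                    class = "gene_module_set")
    out <- module_significance(ms, cpm, n_perm = 100, alpha = 0.05,
                               seed = s)
    if (length(out$modules) == 0) rejected <- rejected + 1
  }
  expect_gte(rejected / n_seeds, 0.9)
})

test_that("empty module sets pass through the significance filter", {
  empty <- detect_modules(matrix(1:4, 2, 2,
                                 dimnames = list(c("a", "b"), c("x", "y"))),
                          c("a", "b"), min_module_size = 5)
  expect_length(empty$modules, 0)
  out <- module_significance(empty, matrix(1, 2, 2), n_perm = 10)
  expect_length(out$modules, 0)
  expect_error(module_significance(empty, matrix(1, 2, 2), n_perm = 0),
               "n_perm")
})

test_that("eigengenes summarize module expression as the first PC", {
  # module of identical genes: eigengene equals the z-scored shared profile
  withr::with_seed(7, prof <- rnorm(25))
  cpm <- rbind(a = 10^(prof + 3), b = 10^(prof + 3), c = 10^(prof + 3))
  colnames(cpm) <- sprintf("c%02d", 1:25)
  eg <- eigengenes(cpm, list(c("a", "b", "c")))
  z <- as.vector(scale(log10(cpm["a", ] + 1)))
  expect_equal(unname(eg[1, ]) / sd(eg[1, ]), z / sd(z), tolerance = 1e-8)
  expect_gte(cor(eg[1, ], z), 0.999999)

  # single-gene module: eigengene is the z-scored gene itself
  eg1 <- eigengenes(cpm, list("a"))
  expect_equal(unname(eg1[1, ]), z, tolerance = 1e-8)
})

test_that("eigengene matches an independent SVD on a 10x20 submatrix", {
  withr::with_seed(8, {
    u <- rnorm(20)
    cpm <- 10^(matrix(rep(u, each = 10), 10, 20) +
                 matrix(rnorm(200, sd = 0.4), 10, 20) + 3)
  })
  dimnames(cpm) <- list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:20))
  eg <- eigengenes(cpm, list(rownames(cpm)))
  # oracle: full SVD of the z-scored matrix, first right singular vector
  z <- t(scale(t(log10(cpm + 1))))
  sv <- svd(z)
  oracle <- sv$v[, 1] * sv$d[1]
  oracle <- oracle / sd(oracle)
  if (cor(oracle, colMeans(z)) < 0) oracle <- -oracle
  expect_equal(unname(eg[1, ]), oracle, tolerance = 1e-8)
})

test_that("zero-variance genes are dropped from modules with a warning", {
  withr::with_seed(9, prof <- rnorm(20))
  cpm <- rbind(a = 10^(prof + 3), b = 10^(prof + 3), flat = rep(100, 20))
  colnames(cpm) <- sprintf("c%02d", 1:20)
  expect_warning(eg <- eigengenes(cpm, list(c("a", "b", "flat"))),
                 "zero-variance")
  expect_equal(abs(cor(eg[1, ], scale(log10(cpm["a", ] + 1))[, 1])), 1,
               tolerance = 1e-8)
})
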