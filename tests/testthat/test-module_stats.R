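test_that("module filtering enforces the DE intersection and 10-gene minimum", {
  modules <- list(
    big = sprintf("m%d", 1:12),     # 10 of 12 in de_genes: retained with 10
    small = sprintf("m%d", 1:12),   # only 9 in de_genes: dropped
    other = sprintf("x%d", 1:15))
  de_genes <- c(sprintf("m%d", 1:10), sprintf("x%d", 1:15))
  kept <- filter_modules(modules["big"], de_genes)
  expect_named(kept, "big")
  expect_length(kept$big, 10)
  kept2 <- filter_modules(modules["small"], sprintf("m%d", 1:9))
  expect_length(kept2, 0)
  expect_length(filter_modules(modules, character(0)), 0)
  expect_named(filter_modules(modules, c(sprintf("m%d", 1:9),
                                         sprintf("x%d", 1:15))), "other")
})

test_that("module scores min-max scale to [0,1] with the degenerate rule", {
  sim <- simulate_dataset(simulation_config(
    n_cell_types = 3, cells_per_type_per_timepoint = 15, n_genes = 2200,
    timepoints = c(0, 1), seed = 81))
  ds <- log_normalize(sim$dataset)
  set.seed(3)
  res <- module_score(ds, rownames(ds$counts)[101:115])
  expect_true(all(res$scaled_score >= 0 & res$scaled_score <= 1))
  expect_equal(min(res$scaled_score), 0)
  expect_equal(max(res$scaled_score), 1)
  expect_equal(res$scaled_score[which.min(res$raw_score)], 0)
  expect_equal(res$scaled_score[which.max(res$raw_score)], 1)
  expect_error(module_score(ds, "not_a_gene"), "empty")
})

test_that("scaled scores are invariant under affine raw-score transforms", {
  raw <- c(0.2, 0.8, 0.5, -0.1)
  scale01 <- function(r) (r - min(r)) / (max(r) - min(r))
  expect_equal(scale01(raw), scale01(3 * raw + 7))
  expect_equal(scale01(c(0.2, 0.8)), c(0, 1))
  # degenerate all-equal raw scores map to 0
  ds <- simulate_dataset(simulation_config(
    n_cell_types = 3, cells_per_type_per_timepoint = 4, n_genes = 2100,
    timepoints = c(0, 1), seed = 82))$dataset
  # all-zero counts for module and background: every raw score identical
  ds$counts[] <- 0
  ds <- suppressWarnings(log_normalize(ds))
  set.seed(4)
  res <- suppressWarnings(module_score(ds, rownames(ds$counts)[1:12]))
  expect_true(all(res$scaled_score == 0))
  set.seed(4)
  res2 <- suppressWarnings(module_score(ds, rownames(ds$counts)[1:12],
                                        degenerate = 0.5))
  expect_true(all(res2$scaled_score == 0.5))
})

test_that("planted module cells score above non-carriers", {
  cfg <- simulation_config(
    n_cell_types = 4, cells_per_type_per_timepoint = 40, n_genes = 2200,
    timepoints = c(0, 0.5, 2),
    module_genes = sprintf("gene%04d", 500:514), module_fold = 4,
    module_timepoints = 0.5, seed = 83)
  sim <- simulate_dataset(cfg)
  ds <- log_normalize(sim$dataset)
  set.seed(5)
  res <- module_score(ds, cfg$module_genes)
  carrier <- res$cell_id %in% sim$truth$module_cell_ids
  expect_gt(median(res$scaled_score[carrier]),
            median(res$scaled_score[!carrier]))
})

test_that("permutation test matches exact enumeration on small groups", {
  set.seed(105)
  vals <- c(0, 0, 0, 10, 10, 10)
  labs <- rep(c("a", "b"), each = 3)
  pt <- permutation_test(vals, labs, 1000)
  exact <- oracle_perm_p(vals, labs == "a")
  expect_equal(exact, 0.1)  # complete separation of 3 vs 3
  se <- sqrt(exact * (1 - exact) / 1000)
  expect_lt(abs(pt$p_value - exact), 3 * se + 2 / 1001)
  # all-identical values: p = 1
  expect_equal(permutation_test(rep(2, 8), rep(c("a", "b"), 4), 500)$p_value, 1)
  # random small cases track the enumeration oracle
  for (i in 1:10) {
    v <- rnorm(sample(6:12, 1))
    l <- sample(rep(c("a", "b"), length.out = length(v)))
    pt <- permutation_test(v, l, 2000)
    ex <- oracle_perm_p(v, l == "a")
    expect_lt(abs(pt$p_value - ex),
              3 * sqrt(ex * (1 - ex) / 2000) + 2 / 2001)
  }
})

test_that("permutation test validates its inputs", {
  expect_error(permutation_test(1:4, rep("a", 4)), "two groups")
  expect_error(permutation_test(1:4, c("a", "a", "b", "c")), "two groups")
  expect_error(permutation_test(1:4, rep(c("a", "b"), 2), 0), ">= 1")
})
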