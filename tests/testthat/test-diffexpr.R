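test_that("Wilcoxon worked examples match exact enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4, 5))$p_value, 0.2)
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 5))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Wilcoxon exact path agrees with the bitmask oracle, with ties", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    # integer draws from a narrow range force ties
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, m, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_wilcox_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon normal approximation matches wilcox.test with ties", {
  set.seed(102)
  for (i in 1:25) {
    x <- sample(1:8, 30, replace = TRUE)
    y <- sample(1:8, 25, replace = TRUE) + sample(0:1, 25, replace = TRUE)
    ours <- wilcoxon_rank_sum(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                               exact = FALSE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up oracle and handles edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  set.seed(103)
  for (i in 1:30) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("BH output is permutation-equivariant and bounded by 1", {
  set.seed(104)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) <= 1))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("de_table estimates planted folds and nulls look null", {
  g <- function(i) sprintf("gene%04d", i)
  cfg <- simulation_config(
    n_cell_types = 3, cells_per_type_per_timepoint = 100, n_genes = 300,
    timepoints = c(0, 0.5),
    planted_de = list(list(gene = g(1), cell_type = "neuron_1", fold = 5,
                           timepoints = 0.5)),
    seed = 61)
  ds <- log_normalize(simulate_dataset(cfg)$dataset)
  de <- de_table(ds, "neuron_1", 0.5)
  hit <- de[de$gene == g(1), ]
  expect_gt(hit$fold_change, 3.5)
  expect_lt(hit$fold_change, 6.5)
  expect_lt(hit$p_value, 0.05)
  nulls <- de[de$gene != g(1), ]
  expect_lt(median(abs(log2(nulls$fold_change))), 0.5)
  expect_true(all(de$adj_p >= de$p_value - 1e-15))
  expect_true(all(de$fold_change > 0))
  expect_true(all(de$pct_expr_group >= 0 & de$pct_expr_group <= 1))
  # genes absent from both groups are excluded
  detected <- Matrix::rowSums(ds$counts[, ds$cells$cell_type == "neuron_1"]) > 0
  expect_true(all(de$gene %in% rownames(ds$counts)[detected]))
})

test_that("de_table skips groups with fewer than 3 cells, with a warning", {
  sim <- simulate_dataset(simulation_config(
    n_cell_types = 3, cells_per_type_per_timepoint = 2, n_genes = 50,
    timepoints = c(0, 1), seed = 62))
  ds <- log_normalize(sim$dataset)
  expect_warning(res <- de_table(ds, "neuron_1", 1), "fewer than 3 cells")
  expect_equal(nrow(res), 0)
})

test_that("selection rules are strict at their boundaries", {
  rec <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e"),
    cell_type = "t", timepoint = 1,
    fold_change = c(3.0, 4, 4, 4, 3.01),
    log2_fc = log2(c(3.0, 4, 4, 4, 3.01)),
    pct_expr_group = c(0.5, 0.09, 0.5, 0.5, 0.5),
    pct_expr_ref = 0.1,
    p_value = c(0.01, 0.01, 0.06, 0.01, 0.049),
    adj_p = c(1e-21, 1e-20, 1e-19, 5e-21, 0.5))
  sel <- select_lr_candidates(rec)
  expect_setequal(sel$gene, c("d", "e"))  # fold 3.0 exact and pct 0.09 rejected
  pb <- select_pseudobulk_de(rec)
  expect_setequal(pb$gene, c("a", "d"))   # adj_p == 1e-20 rejected (strict)
  expect_equal(nrow(select_pseudobulk_de(rec[0, ])), 0)
})
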