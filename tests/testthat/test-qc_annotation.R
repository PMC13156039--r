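test_that("QC discard rules reproduce the expected pattern at the boundaries", {
  fx <- qc_fixture()
  qc <- compute_qc(fx$dataset)
  expect_equal(qc$n_genes_detected,
               vapply(fx$specs, function(s) s$detected, integer(1)),
               ignore_attr = TRUE)
  expected_frac <- vapply(fx$specs, function(s) {
    if (s$detected == 0L) return(0)
    s$mito_count / (s$mito_count + s$detected - (s$mito_count > 0))
  }, numeric(1))
  expect_identical(expected_frac[["c6"]], 0.2)  # exact boundary by design
  expect_equal(qc$mito_fraction, expected_frac, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(qc$pass_primary,
               c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                 FALSE), ignore_attr = TRUE)
  expect_equal(qc$pass_secondary,
               c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE,
                 FALSE), ignore_attr = TRUE)
  # primary implies secondary
  expect_true(all(qc$pass_secondary[qc$pass_primary]))
})

test_that("QC filtering is idempotent", {
  sim <- simulate_dataset(simulation_config(
    n_cell_types = 3, cells_per_type_per_timepoint = 20, n_genes = 100,
    timepoints = c(0, 1), high_mito_cell_fraction = 0.3, seed = 3))
  params <- pipeline_params(min_genes_primary = 50, min_genes_secondary = 25)
  qc1 <- compute_qc(sim$dataset, params)
  once <- subset_cells(sim$dataset, qc1$cell_id[qc1$pass_secondary])
  qc2 <- compute_qc(once, params)
  expect_true(all(qc2$pass_secondary))
  twice <- subset_cells(once, qc2$cell_id[qc2$pass_secondary])
  expect_identical(once$cells, twice$cells)
})

test_that("neuron purification removes cells failing either marker rule", {
  # 2 marker genes x 4 cells; normalized values controlled via single counts
  counts <- matrix(c(0, 10, 40, 40,
                     0, 0, 0, 60,
                     100, 90, 60, 0), nrow = 3, byrow = TRUE)
  ds <- expression_dataset(
    counts,
    genes = data.frame(gene_id = c("r", "a", "f"),
                       gene_symbol = c("Rbfox3", "Apoe", "filler"),
                       is_mito = FALSE),
    cells = data.frame(cell_id = sprintf("c%d", 1:4), cell_type = "neuron",
                       compartment = "neuronal", timepoint = 0,
                       condition = "control"))
  ds <- log_normalize(ds, scale = 100)
  rb <- as.numeric(ds$normalized["Rbfox3", ])
  ap <- as.numeric(ds$normalized["Apoe", ])
  kept <- filter_neuron_candidates(ds, sprintf("c%d", 1:4))
  expected <- sprintf("c%d", 1:4)[rb >= 0.5 & ap <= 2]
  expect_identical(kept, expected)
  expect_true("c1" %in% setdiff(sprintf("c%d", 1:4), kept)) # Rbfox3 = 0
  expect_error(filter_neuron_candidates(ds, "c1", neuron_marker = "Nope"),
               "Nope")
})

test_that("prototype classifier separates disjoint marker programs", {
  ref <- separable_reference()
  clf <- fit_prototype_classifier(ref, n_top_genes = 30)
  lab <- assign_labels(clf, ref)
  truth <- ref$cells$cell_type
  expect_gte(mean(lab$label == truth), 0.95)
  expect_lte(mean(lab$label == "unassigned"), 0.05)
  expect_true(all(lab$prediction_score[lab$label == truth] >= 0.55))
  expect_gte(min(lab$prediction_score), 0.5)

  expect_error(fit_prototype_classifier(ref, labels = rep("one", 40)),
               "at least 2 labels")
  expect_error(fit_prototype_classifier(ref, labels = c("a", rep("b", 39))),
               "fewer than 3 cells")
})

test_that("identical cells across two labels score near 0.5 and are unassigned", {
  base <- matrix(rpois(200, 2), nrow = 20)
  counts <- cbind(base, base)  # duplicate block per label
  ds <- expression_dataset(
    counts,
    genes = data.frame(gene_id = sprintf("G%d", 1:20),
                       gene_symbol = sprintf("g%d", 1:20), is_mito = FALSE),
    cells = data.frame(cell_id = sprintf("c%d", 1:20),
                       cell_type = rep(c("a", "b"), each = 10),
                       compartment = "immune", timepoint = 0,
                       condition = "control"))
  clf <- fit_prototype_classifier(ds, n_top_genes = 20)
  lab <- assign_labels(clf, ds)
  expect_true(all(abs(lab$prediction_score - 0.5) < 1e-8))
  expect_true(all(lab$label == "unassigned"))

  empty <- subset_cells(ds, character(0))
  expect_equal(nrow(assign_labels(clf, empty)), 0)
})
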