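test_that("candidate pairs require an upregulated ligand and an expressed receptor", {
  # 4 genes x 2 types x 10 cells, receptor detection controlled directly
  counts <- cbind(
    matrix(c(rep(5, 10),   # lig expressed in A
             rep(0, 10),
             rep(1, 10),   # recA detected in 100% of A
             rep(0, 10)), nrow = 4, byrow = TRUE),
    matrix(c(rep(0, 10),
             rep(0, 10),
             c(1, rep(0, 9)),  # recA in 10% of B: not > 10%
             rep(2, 10)), nrow = 4, byrow = TRUE))
  ds <- expression_dataset(
    counts,
    genes = data.frame(gene_id = sprintf("G%d", 1:4),
                       gene_symbol = c("lig", "lig2", "recA", "recB"),
                       is_mito = FALSE),
    cells = data.frame(cell_id = sprintf("c%02d", 1:20),
                       cell_type = rep(c("A", "B"), each = 10),
                       compartment = "immune", timepoint = 1,
                       condition = "arthritis"))
  cand <- tibble::tibble(gene = "lig", cell_type = "A")
  ref <- lr_reference(c("lig", "lig", "lig2", "ghost"),
                      c("recA", "recB", "recA", "recB"),
                      list("t1", "t2", "t3", "t4"))
  expect_message(
    pairs <- build_candidate_pairs(cand, ds, ref, timepoint = 1),
    "skipped")
  # lig->recA: receptor in 100% of A (pair A->A) but only 10% of B (no A->B)
  # lig->recB: receptor in 100% of B
  expect_equal(pairs$receiver[pairs$receptor == "recA"], "A")
  expect_equal(pairs$receiver[pairs$receptor == "recB"], "B")
  expect_true(all(pairs$sender == "A"))
  # lig2 is not upregulated anywhere: no pair
  expect_false("lig2" %in% pairs$ligand)
  # empty candidate set gives an empty pair list
  empty <- build_candidate_pairs(cand[0, ], ds, ref, timepoint = 1)
  expect_equal(nrow(empty), 0)
})

test_that("stratified background partitions rank space and is reproducible", {
  sim <- simulate_dataset(simulation_config(
    n_cell_types = 3, cells_per_type_per_timepoint = 20, n_genes = 2200,
    timepoints = c(0, 1), seed = 71))
  ds <- log_normalize(sim$dataset)
  pool <- rownames(ds$counts)[1:150]
  params <- pipeline_params()
  set.seed(1)
  bg <- stratified_background(ds, "neuron_1", pool, timepoint = 1,
                              params = params)
  expect_equal(dim(bg), c(20, 100))
  expect_equal(anyDuplicated(as.vector(bg)), 0)
  expect_length(intersect(as.vector(bg), pool), 0)
  set.seed(1)
  bg2 <- stratified_background(ds, "neuron_1", pool, timepoint = 1,
                               params = params)
  expect_identical(bg, bg2)
  # rows respect the expression ranking: interval means are non-increasing
  gm <- ligrec:::receiver_gene_means(ds, "neuron_1", 1)
  row_means <- rowMeans(matrix(gm[as.vector(bg)], nrow = 20))
  expect_true(all(diff(row_means) <= 1e-12))
})

test_that("background draw clamps per-interval size with a warning", {
  sim <- simulate_dataset(simulation_config(
    n_cell_types = 3, cells_per_type_per_timepoint = 10, n_genes = 200,
    timepoints = c(0, 1), seed = 72))
  ds <- log_normalize(sim$dataset)
  pool <- rownames(ds$counts)[1:160]  # 40 background genes, 20 intervals
  expect_warning(
    bg <- stratified_background(ds, "neuron_1", pool,
                                params = pipeline_params()),
    "reduced")
  expect_equal(dim(bg), c(20, 2))
  expect_error(
    stratified_background(ds, "neuron_1", rownames(ds$counts)[1:190],
                          params = pipeline_params()),
    "background genes")
})

test_that("enrichment score has the closed-form value on constructed data", {
  # associated genes exceed every background gene by delta in every cell
  delta <- 0.75
  n_cells <- 6
  base <- matrix(2L, nrow = 44, ncol = n_cells)
  ds <- expression_dataset(
    rbind(matrix(5L, nrow = 4, ncol = n_cells), base),
    genes = data.frame(gene_id = sprintf("G%d", 1:48),
                       gene_symbol = c(sprintf("assoc%d", 1:4),
                                       sprintf("bg%d", 1:44)),
                       is_mito = FALSE),
    cells = data.frame(cell_id = sprintf("c%d", 1:n_cells), cell_type = "R",
                       compartment = "immune", timepoint = 1,
                       condition = "arthritis"))
  # overwrite the normalized layer with controlled values
  norm <- Matrix::Matrix(0, nrow = 48, ncol = n_cells, sparse = TRUE,
                         dimnames = dimnames(ds$counts))
  norm[1:4, ] <- 1.25
  norm[5:48, ] <- 1.25 - delta
  ds$normalized <- methods::as(norm, "CsparseMatrix")
  bg <- matrix(sprintf("bg%d", 1:40), nrow = 20)
  expect_equal(enrichment_score(ds, "R", 1, sprintf("assoc%d", 1:4), bg),
               delta)
  # zero associated, positive background: negative score
  ds$normalized[1:4, ] <- 0
  expect_lt(enrichment_score(ds, "R", 1, sprintf("assoc%d", 1:4), bg), 0)
  expect_error(enrichment_score(ds, "R", 1, "nope", bg), "no associated genes")
})

test_that("activity clips replicates at zero before averaging", {
  raw_scores <- list(c(-0.2, -0.1, -0.3, -0.05, -0.4),
                     c(0.5, 0.5, 0.5, 0.5, 0.5),
                     c(-1, 1, -1, 1, 0))
  clipped_mean <- vapply(raw_scores, function(r) mean(pmax(r, 0)), numeric(1))
  expect_equal(clipped_mean, c(0, 0.5, 0.4))
  # on data: all-negative replicates yield exactly zero activity
  sim <- simulate_dataset(simulation_config(
    n_cell_types = 3, cells_per_type_per_timepoint = 15, n_genes = 2200,
    timepoints = c(0, 1), seed = 73))
  ds <- log_normalize(sim$dataset)
  set.seed(2)
  # the two least-expressed genes sit far below the background mean, so
  # every replicate's raw score is negative
  gm <- ligrec:::receiver_gene_means(ds, "neuron_1", 1)
  low_genes <- names(sort(gm))[1:2]
  res <- score_interaction(ds, "neuron_1", "neuron_1", "x", "y", 1,
                           targets = low_genes,
                           candidate_pool = character(0))
  expect_equal(res$activity_score, 0)
  expect_true(all(res$replicate_scores[[1]] < 0))
})

test_that("interactome table orders deterministically and exports sankey", {
  acts <- tibble::tibble(
    sender = c("b", "a", "a"), receiver = c("x", "x", "w"),
    ligand = c("l1", "l2", "l3"), receptor = c("r1", "r2", "r3"),
    timepoint = 1, activity_score = c(0.5, 0.5, 0),
    replicate_scores = list(1, 1, 1), n_background_genes_used = 2000L)
  ranked <- interactome_table(acts)
  expect_equal(ranked$sender, c("a", "b", "a"))  # tie broken lexicographically
  sk <- sankey_export(ranked)
  expect_equal(nrow(sk$links), 2)  # zero-activity link dropped
  expect_setequal(sk$nodes$name, c("a", "b", "w", "x"))
  none <- sankey_export(acts[acts$activity_score < 0, ])
  expect_equal(nrow(none$links), 0)
})
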