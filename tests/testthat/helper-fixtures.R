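# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures on disk.

# Tiny hand-built dataset: counts given explicitly, one mito gene.
toy_dataset <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(10, 0, 2,
                       0, 5, 1,
                       3, 1, 0,
                       1, 2, 4), nrow = 4, byrow = TRUE)
  }
  n_genes <- nrow(counts)
  n_cells <- ncol(counts)
  expression_dataset(
    counts,
    genes = data.frame(gene_id = sprintf("G%02d", seq_len(n_genes)),
                       gene_symbol = c("mt-g1", sprintf("g%d", seq_len(n_genes - 1))),
                       is_mito = c(TRUE, rep(FALSE, n_genes - 1))),
    cells = data.frame(cell_id = sprintf("c%d", seq_len(n_cells)),
                       cell_type = "t",
                       compartment = "immune",
                       timepoint = 0,
                       condition = "control"))
}

# Planted-recovery study design: 3 true sender->receiver programs (target
# fold 5) plus decoy ligands (upregulated, silent targets) so that the
# candidate-pair list is large. Used by the interactome recovery and null
# calibration checks.
recovery_config <- function(seed, with_true = TRUE, n_decoys = 12,
                            cells_per_type = 100, n_genes = 2500) {
  g <- function(i) sprintf("gene%04d", i)
  true_pairs <- list(
    planted_interaction("macrophage", "neuron_1", g(1), g(2), g(10:19),
                        fold = 5, timepoints = 0.5),
    planted_interaction("satellite_glia", "neuron_1", g(3), g(4), g(20:29),
                        fold = 5, timepoints = 0.5),
    planted_interaction("macrophage", "schwann_cell", g(5), g(6), g(30:39),
                        fold = 5, timepoints = 0.5))
  decoys <- lapply(seq_len(n_decoys), function(i) {
    base <- 100 + 20 * (i - 1)
    planted_interaction(
      sender = if (i %% 2 == 0) "macrophage" else "satellite_glia",
      receiver = "schwann_cell",
      ligand = g(base), receptor = g(base + 1), targets = g(base + 2:11),
      fold = 5, timepoints = 0.5, target_fold = 1)
  })
  simulation_config(
    n_cell_types = 5,
    cells_per_type_per_timepoint = cells_per_type,
    n_genes = n_genes,
    timepoints = c(0, 0.5),
    planted_interactions = c(if (with_true) true_pairs, decoys),
    seed = seed)
}

# Ligand-receptor reference matching a config's planted interactions.
reference_from_config <- function(config) {
  pis <- config$planted_interactions
  lr_reference(vapply(pis, `[[`, character(1), "ligand"),
               vapply(pis, `[[`, character(1), "receptor"),
               lapply(pis, `[[`, "targets"))
}

# Run simulate -> DE at 12 h -> candidate pairs -> scored interactome.
run_interactome <- function(config, params = pipeline_params()) {
  sim <- simulate_dataset(config, params = params)
  ds <- log_normalize(sim$dataset)
  de <- dplyr::bind_rows(lapply(sort(unique(ds$cells$cell_type)), function(ct) {
    suppressWarnings(de_table(ds, ct, 0.5, 0, params))
  }))
  cand <- select_lr_candidates(de, params)
  ref <- reference_from_config(config)
  pairs <- build_candidate_pairs(cand, ds, ref, timepoint = 0.5,
                                 params = params)
  acts <- score_interactome(ds, pairs, ref, unique(cand$gene), 0.5, params)
  list(sim = sim, dataset = ds, de = de, candidates = cand, pairs = pairs,
       activities = acts)
}

# Two well-separated synthetic cell types with disjoint marker programs.
separable_reference <- function(n_per_type = 20, n_genes = 60, seed = 7) {
  set.seed(seed)
  n_cells <- 2 * n_per_type
  counts <- matrix(rpois(n_genes * n_cells, 0.2), nrow = n_genes)
  counts[1:10, seq_len(n_per_type)] <- rpois(10 * n_per_type, 20)
  counts[11:20, n_per_type + seq_len(n_per_type)] <- rpois(10 * n_per_type, 20)
  expression_dataset(
    counts,
    genes = data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)),
                       gene_symbol = sprintf("g%03d", seq_len(n_genes)),
                       is_mito = FALSE),
    cells = data.frame(cell_id = sprintf("c%03d", seq_len(n_cells)),
                       cell_type = rep(c("alpha", "beta"), each = n_per_type),
                       compartment = "immune",
                       timepoint = 0,
                       condition = "control"))
}

# 10-cell QC fixture with known mito fractions and detected-gene counts,
# including both boundary cells (exactly 20% mito; exactly 2,000 genes).
qc_fixture <- function() {
  n_genes <- 3000L
  # mito_count / (mito_count + n_detected - 1) is the mito fraction: the
  # mito gene (gene 1) carries mito_count counts, every other detected gene
  # carries 1. Counts are chosen so the fractions are exact.
  specs <- list(
    c1 = list(detected = 2500L, mito_count = 0L),    # pass both
    c2 = list(detected = 2000L, mito_count = 0L),    # boundary: fails primary only
    c3 = list(detected = 2001L, mito_count = 0L),    # just above: passes primary
    c4 = list(detected = 999L, mito_count = 0L),     # fails both
    c5 = list(detected = 1000L, mito_count = 0L),    # boundary: secondary only
    c6 = list(detected = 2501L, mito_count = 625L),  # exactly 20%: kept
    c7 = list(detected = 2501L, mito_count = 790L),  # 24%: discarded
    c8 = list(detected = 1500L, mito_count = 0L),    # secondary only
    c9 = list(detected = 0L, mito_count = 0L),       # empty cell
    c10 = list(detected = 2600L, mito_count = 2599L) # half mito: discarded
  )
  i <- integer(0); j <- integer(0); x <- integer(0)
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    if (s$detected == 0L) next
    n_nonmito <- s$detected - (s$mito_count > 0)
    rows <- 1L + seq_len(n_nonmito)          # gene 1 is the mito gene
    vals <- rep(1L, n_nonmito)
    if (s$mito_count > 0) {
      rows <- c(1L, rows)
      vals <- c(s$mito_count, vals)
    }
    i <- c(i, rows); j <- c(j, rep(k, length(rows))); x <- c(x, vals)
  }
  counts <- Matrix::sparseMatrix(i = i, j = j, x = x,
                                 dims = c(n_genes, length(specs)))
  ds <- expression_dataset(
    counts,
    genes = data.frame(gene_id = sprintf("G%04d", 1:n_genes),
                       gene_symbol = c("mt-g1", sprintf("g%d", 2:n_genes)),
                       is_mito = c(TRUE, rep(FALSE, n_genes - 1))),
    cells = data.frame(cell_id = names(specs), cell_type = "t",
                       compartment = "immune", timepoint = 0,
                       condition = "control"))
  list(dataset = ds, specs = specs)
}

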