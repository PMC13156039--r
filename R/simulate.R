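#' Simulation configuration
#'
#' Describes a synthetic time-course single-cell experiment that mirrors the
#' structure of an inflamed dorsal-root-ganglion atlas: eight timepoints
#' (days 0 to 63), ~15 neuronal / non-neuronal / immune cell types, gene-wise
#' negative-binomial counts with a log-normal mean prior, planted
#' ligand -> receptor -> target communication programs, a transient
#' interferon-stimulated-gene-like module, and a monocyte influx that shifts
#' the immune composition from ~3.5% to ~65% monocytes at its peak.
#'
#' Planted effects act multiplicatively on the negative-binomial mean, so the
#' planted fold is the quantity the downstream fold-change selection rule
#' estimates. Genes carrying a planted role (and the receptors of planted
#' pairs, in the receiver type) have their baseline mean floored at a
#' moderate level so folds are estimable and receptors are detected in more
#' than 10% of receiver cells.
#'
#' @param n_cell_types Number of cell types (>= 3; split across neuronal,
#'   immune and other non-neuronal compartments, always including
#'   `"monocyte"`).
#' @param cells_per_type_per_timepoint Cells per type per timepoint.
#' @param n_genes Genes in the universe (see [gene_universe()]).
#' @param timepoints Day labels; must contain 0 (the control timepoint).
#' @param baseline_mean_log,baseline_sd_log Location and scale of the
#'   log-normal prior on gene mean expression.
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param library_size_spread Range of the multiplicative per-cell library
#'   factor, drawn uniformly.
#' @param planted_interactions List of [planted_interaction()] records.
#' @param planted_de List of lists `(gene, cell_type, fold, timepoints)`:
#'   generic differential-expression plantings (e.g. upregulated ligands with
#'   no induced target program).
#' @param module_genes Character vector: the transient module's genes.
#' @param module_fold Induction fold of the module in module-carrying cells.
#' @param module_timepoints Timepoints at which the module is active; all
#'   cells at these timepoints carry it.
#' @param monocyte_fraction_baseline,monocyte_fraction_peak Monocyte fraction
#'   among immune cells at baseline and at `monocyte_peak_timepoints`.
#' @param monocyte_peak_timepoints Timepoints of the monocyte influx.
#' @param mito_gene_fraction Fraction of genes flagged mitochondrial
#'   (`mt-` prefix).
#' @param high_mito_cell_fraction Fraction of cells given strongly elevated
#'   mitochondrial means (the cells QC should discard).
#' @param planted_base_mean,receptor_base_mean Baseline-mean floors for
#'   planted-role genes and for receptor genes in their receiver type.
#' @param seed Integer master seed; stage streams derive from it via
#'   [child_seed()].
#'
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_cell_types = 15L,
                              cells_per_type_per_timepoint = 50L,
                              n_genes = 2500L,
                              timepoints = c(0, 0.25, 0.5, 1, 2, 12, 33, 63),
                              baseline_mean_log = -0.5,
                              baseline_sd_log = 1,
                              nb_dispersion = 0.5,
                              library_size_spread = c(0.7, 1.4),
                              planted_interactions = list(),
                              planted_de = list(),
                              module_genes = character(),
                              module_fold = 4,
                              module_timepoints = c(0.25, 0.5, 1),
                              monocyte_fraction_baseline = 0.035,
                              monocyte_fraction_peak = 0.65,
                              monocyte_peak_timepoints = 0.5,
                              mito_gene_fraction = 0.05,
                              high_mito_cell_fraction = 0.05,
                              planted_base_mean = 0.5,
                              receptor_base_mean = 1.5,
                              seed = 1L) {
  config <- list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type_per_timepoint = as.integer(cells_per_type_per_timepoint),
    n_genes = as.integer(n_genes),
    timepoints = as.numeric(timepoints),
    baseline_mean_log = baseline_mean_log,
    baseline_sd_log = baseline_sd_log,
    nb_dispersion = nb_dispersion,
    library_size_spread = library_size_spread,
    planted_interactions = planted_interactions,
    planted_de = planted_de,
    module_genes = as.character(module_genes),
    module_fold = module_fold,
    module_timepoints = as.numeric(module_timepoints),
    monocyte_fraction_baseline = monocyte_fraction_baseline,
    monocyte_fraction_peak = monocyte_fraction_peak,
    monocyte_peak_timepoints = as.numeric(monocyte_peak_timepoints),
    mito_gene_fraction = mito_gene_fraction,
    high_mito_cell_fraction = high_mito_cell_fraction,
    planted_base_mean = planted_base_mean,
    receptor_base_mean = receptor_base_mean,
    seed = as.integer(seed)
  )
  class(config) <- "sim_config"
  validate_sim_config(config)
  config
}

#' Describe one planted sender -> receiver communication program
#'
#' @param sender,receiver Cell-type names.
#' @param ligand,receptor Gene symbols from [gene_universe()].
#' @param targets Character vector of associated target genes induced in the
#'   receiver.
#' @param fold Planted fold change, applied to the ligand in the sender and
#'   to the targets in the receiver at `timepoints`.
#' @param timepoints Active timepoints.
#' @param ligand_fold,target_fold Override `fold` separately; a
#'   `target_fold` of 1 makes a decoy pair whose ligand is upregulated but
#'   whose target program is silent.
#' @return A list usable in `planted_interactions`.
#' @export
planted_interaction <- function(sender, receiver, ligand, receptor, targets,
                                fold = 5, timepoints = 0.5,
                                ligand_fold = fold, target_fold = fold) {
  stopifnot(length(targets) >= 1, ligand_fold > 0, target_fold > 0)
  list(sender = sender, receiver = receiver, ligand = ligand,
       receptor = receptor, targets = as.character(targets),
       ligand_fold = ligand_fold, target_fold = target_fold,
       timepoints = as.numeric(timepoints))
}

#' Gene symbols of a simulation's gene universe
#'
#' Mitochondrial genes come first with an `mt-` prefix; planted genes should
#' be chosen from the non-mitochondrial remainder.
#'
#' @param config A [simulation_config()], or an integer gene count (with
#'   `mito_gene_fraction` then read from the second argument).
#' @param mito_gene_fraction Used when `config` is a plain count.
#' @return Character vector of `n_genes` symbols.
#' @export
gene_universe <- function(config, mito_gene_fraction = 0.05) {
  if (inherits(config, "sim_config")) {
    n <- config$n_genes
    frac <- config$mito_gene_fraction
  } else {
    n <- as.integer(config)
    frac <- mito_gene_fraction
  }
  n_mito <- round(frac * n)
  c(if (n_mito > 0) sprintf("mt-gene%04d", seq_len(n_mito)),
    sprintf("gene%04d", seq_len(n - n_mito)))
}

# Cell-type panel: compartments split roughly 1:2:2 neuronal:immune:other,
# monocyte always present among the immune types.
cell_type_table <- function(n_cell_types) {
  stopifnot(n_cell_types >= 3)
  n_neuronal <- max(1L, round(n_cell_types * 0.2))
  n_immune <- max(1L, round(n_cell_types * 0.4))
  n_other <- n_cell_types - n_neuronal - n_immune
  if (n_other < 1) {
    n_other <- 1L
    n_immune <- n_cell_types - n_neuronal - n_other
  }
  immune_names <- c("monocyte", "macrophage", "t_cell", "b_cell",
                    "neutrophil", "dendritic_cell")
  other_names <- c("satellite_glia", "schwann_cell", "fibroblast",
                   "endothelial", "pericyte", "vsmc")
  pick <- function(pool, n, prefix) {
    if (n <= length(pool)) pool[seq_len(n)]
    else c(pool, sprintf("%s_%d", prefix, seq_len(n - length(pool))))
  }
  tibble::tibble(
    cell_type = c(sprintf("neuron_%d", seq_len(n_neuronal)),
                  pick(immune_names, n_immune, "immune"),
                  pick(other_names, n_other, "stromal")),
    compartment = c(rep("neuronal", n_neuronal),
                    rep("immune", n_immune),
                    rep("non_neuronal", n_other))
  )
}

validate_sim_config <- function(config) {
  c2 <- config
  props <- c(c2$monocyte_fraction_baseline, c2$monocyte_fraction_peak,
             c2$mito_gene_fraction, c2$high_mito_cell_fraction)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (!0 %in% c2$timepoints) stop("timepoints must contain 0 (control)")
  if (c2$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (c2$module_fold <= 0) stop("fold changes must be > 0")
  universe <- gene_universe(c2)
  types <- cell_type_table(c2$n_cell_types)
  roles <- list()
  add_role <- function(roles, genes, role) {
    for (g in genes) {
      if (!g %in% universe) stop("planted gene not in gene universe: ", g)
      if (!is.null(roles[[g]])) {
        stop("planted gene collision: ", g, " already has role ", roles[[g]])
      }
      roles[[g]] <- role
    }
    roles
  }
  for (pi in c2$planted_interactions) {
    stopifnot(all(c(pi$sender, pi$receiver) %in% types$cell_type))
    if (pi$ligand_fold <= 0 || pi$target_fold <= 0) {
      stop("fold changes must be > 0")
    }
    roles <- add_role(roles, pi$ligand, "ligand")
    roles <- add_role(roles, pi$receptor, "receptor")
    roles <- add_role(roles, pi$targets, "target")
  }
  for (pd in c2$planted_de) {
    if (pd$fold <= 0) stop("fold changes must be > 0")
    if (!pd$cell_type %in% types$cell_type) {
      stop("unknown cell type in planted_de: ", pd$cell_type)
    }
    roles <- add_role(roles, pd$gene, "planted_de")
  }
  roles <- add_role(roles, c2$module_genes, "module")
  invisible(config)
}

#' Simulate a time-course single-cell dataset with planted signals
#'
#' Counts are drawn gene-wise from a negative binomial whose mean is a
#' log-normal gene effect times a uniform per-cell library factor, modified
#' multiplicatively by the planted programs of the configuration. Identical
#' seeds give identical output.
#'
#' @param config A [simulation_config()].
#' @param params Optional [pipeline_params()] attached to the dataset.
#' @return A list with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (planted interactions, module cell ids, per-compartment
#'   composition table, and the planted differential-expression map).
#' @examples
#' sim <- simulate_dataset(simulation_config(n_cell_types = 4,
#'   cells_per_type_per_timepoint = 10, n_genes = 100, timepoints = c(0, 0.5)))
#' sim$dataset
#' @export
simulate_dataset <- function(config, params = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  types <- cell_type_table(config$n_cell_types)
  symbols <- gene_universe(config)
  is_mito <- startsWith(symbols, "mt-")
  genes <- tibble::tibble(gene_id = sprintf("G%05d", seq_along(symbols)),
                          gene_symbol = symbols, is_mito = is_mito)

  cells <- draw_cells(config, types)
  n_cells <- nrow(cells)

  set.seed(child_seed(config$seed, "gene_means"))
  mu <- stats::rlnorm(config$n_genes, config$baseline_mean_log,
                      config$baseline_sd_log)
  names(mu) <- symbols

  set.seed(child_seed(config$seed, "library"))
  lib <- stats::runif(n_cells, config$library_size_spread[1],
                      config$library_size_spread[2])
  set.seed(child_seed(config$seed, "mito_cells"))
  high_mito <- stats::runif(n_cells) < config$high_mito_cell_fraction

  set.seed(child_seed(config$seed, "counts"))
  blocks <- vector("list", 0)
  block_order <- integer(0)
  size <- 1 / config$nb_dispersion
  for (tp in config$timepoints) {
    for (ct in types$cell_type) {
      idx <- which(cells$timepoint == tp & cells$cell_type == ct)
      if (length(idx) == 0) next
      mu_eff <- effective_means(mu, ct, tp, config)
      m <- outer(mu_eff, lib[idx])
      boost <- high_mito[idx]
      if (any(boost)) m[is_mito, boost] <- m[is_mito, boost] * 20
      cnt <- matrix(stats::rnbinom(length(m), mu = as.vector(m), size = size),
                    nrow = config$n_genes)
      blocks[[length(blocks) + 1]] <- Matrix::Matrix(cnt, sparse = TRUE)
      block_order <- c(block_order, idx)
    }
  }
  counts <- do.call(cbind, blocks)
  counts <- counts[, order(block_order), drop = FALSE]

  dataset <- expression_dataset(counts, genes, cells, params = params)

  module_cells <- if (length(config$module_genes) > 0) {
    cells$cell_id[cells$timepoint %in% config$module_timepoints]
  } else character(0)

  truth <- list(
    planted_interactions = planted_interactions_tbl(config),
    module_cell_ids = module_cells,
    module_genes = config$module_genes,
    composition_table = truth_composition(cells),
    de_genes = truth_de_genes(config)
  )
  list(dataset = dataset, truth = truth)
}

# Multinomial cell allocation: non-immune types get their nominal count;
# immune cells are reallocated so that monocytes follow the configured
# fraction (binomial draw), emulating an influx at the peak timepoints.
draw_cells <- function(config, types) {
  set.seed(child_seed(config$seed, "composition"))
  per <- config$cells_per_type_per_timepoint
  immune_types <- types$cell_type[types$compartment == "immune"]
  rows <- list()
  counter <- 0L
  for (tp in config$timepoints) {
    type_counts <- stats::setNames(rep(per, nrow(types)), types$cell_type)
    if (length(immune_types) > 1) {
      n_imm <- per * length(immune_types)
      frac <- if (tp %in% config$monocyte_peak_timepoints) {
        config$monocyte_fraction_peak
      } else {
        config$monocyte_fraction_baseline
      }
      n_mono <- stats::rbinom(1, n_imm, frac)
      others <- setdiff(immune_types, "monocyte")
      alloc <- stats::rmultinom(1, n_imm - n_mono,
                                rep(1 / length(others), length(others)))[, 1]
      type_counts["monocyte"] <- n_mono
      type_counts[others] <- alloc
    }
    for (i in seq_len(nrow(types))) {
      ct <- types$cell_type[i]
      n <- type_counts[[ct]]
      if (n == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_id = sprintf("cell%07d", counter + seq_len(n)),
        cell_type = ct,
        compartment = types$compartment[i],
        timepoint = tp,
        condition = if (tp == 0) "control" else "arthritis"
      )
      counter <- counter + n
    }
  }
  dplyr::bind_rows(rows)
}

# Per-gene NB mean for one (cell type, timepoint) block: baseline floors for
# planted-role genes, then multiplicative planted folds.
effective_means <- function(mu, cell_type, timepoint, config) {
  mu_eff <- mu
  floor_at <- function(mu_eff, genes, level) {
    g <- intersect(genes, names(mu_eff))
    mu_eff[g] <- pmax(mu_eff[g], level)
    mu_eff
  }
  for (pi in config$planted_interactions) {
    if (cell_type == pi$sender) {
      mu_eff <- floor_at(mu_eff, pi$ligand, config$planted_base_mean)
      if (timepoint %in% pi$timepoints) {
        mu_eff[pi$ligand] <- mu_eff[pi$ligand] * pi$ligand_fold
      }
    }
    if (cell_type == pi$receiver) {
      mu_eff <- floor_at(mu_eff, pi$receptor, config$receptor_base_mean)
      # the floor exists to make planted folds estimable; a fold-1 (decoy)
      # target program plants nothing and keeps its baseline
      if (pi$target_fold != 1) {
        mu_eff <- floor_at(mu_eff, pi$targets, config$planted_base_mean)
      }
      if (timepoint %in% pi$timepoints) {
        mu_eff[pi$targets] <- mu_eff[pi$targets] * pi$target_fold
      }
    }
  }
  for (pd in config$planted_de) {
    if (cell_type == pd$cell_type) {
      mu_eff <- floor_at(mu_eff, pd$gene, config$planted_base_mean)
      if (timepoint %in% pd$timepoints) {
        mu_eff[pd$gene] <- mu_eff[pd$gene] * pd$fold
      }
    }
  }
  if (length(config$module_genes) > 0) {
    mu_eff <- floor_at(mu_eff, config$module_genes, config$planted_base_mean)
    if (timepoint %in% config$module_timepoints) {
      mu_eff[config$module_genes] <- mu_eff[config$module_genes] *
        config$module_fold
    }
  }
  mu_eff
}

planted_interactions_tbl <- function(config) {
  if (length(config$planted_interactions) == 0) {
    return(tibble::tibble(sender = character(), receiver = character(),
                          ligand = character(), receptor = character(),
                          targets = list(), ligand_fold = numeric(),
                          target_fold = numeric(), timepoints = list()))
  }
  purrr::map_dfr(config$planted_interactions, function(pi) {
    tibble::tibble(sender = pi$sender, receiver = pi$receiver,
                   ligand = pi$ligand, receptor = pi$receptor,
                   targets = list(pi$targets),
                   ligand_fold = pi$ligand_fold,
                   target_fold = pi$target_fold,
                   timepoints = list(pi$timepoints))
  })
}

truth_composition <- function(cells) {
  cells |>
    dplyr::count(.data$timepoint, .data$compartment, .data$cell_type,
                 name = "n_cells") |>
    dplyr::group_by(.data$timepoint, .data$compartment) |>
    dplyr::mutate(fraction = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup()
}

truth_de_genes <- function(config) {
  rows <- list()
  for (pi in config$planted_interactions) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = pi$ligand, cell_type = pi$sender, fold = pi$ligand_fold,
      timepoints = list(pi$timepoints))
    if (pi$target_fold != 1) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = pi$targets, cell_type = pi$receiver, fold = pi$target_fold,
        timepoints = list(pi$timepoints))
    }
  }
  for (pd in config$planted_de) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = pd$gene, cell_type = pd$cell_type, fold = pd$fold,
      timepoints = list(pd$timepoints))
  }
  if (length(config$module_genes) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = config$module_genes, cell_type = NA_character_,
      fold = config$module_fold, timepoints = list(config$module_timepoints))
  }
  if (length(rows) == 0) {
    return(tibble::tibble(gene = character(), cell_type = character(),
                          fold = numeric(), timepoints = list()))
  }
  dplyr::bind_rows(rows)
}
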