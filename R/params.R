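#' Pipeline parameters
#'
#' Bundles every analysis threshold used across the pipeline. Defaults follow
#' the published analysis conventions for inflamed dorsal-root-ganglion
#' single-cell data: cells with more than 20% mitochondrial counts are
#' discarded, the primary dataset keeps cells with more than 2,000 detected
#' genes (the secondary rescue pass keeps >= 1,000), label-transfer
#' assignments below a prediction score of 0.55 are dropped, pseudobulk
#' differential expression uses an adjusted-P cutoff of 1e-20, and
#' ligand-candidate selection requires fold change > 3, detection in > 10% of
#' cells and raw P < 0.05. The activity score samples 20 expression-ranked
#' background intervals of 100 genes each and averages 5 zero-clipped
#' replicates; modules need at least 10 differentially expressed genes and the
#' permutation test uses 1,000 label shuffles.
#'
#' @param mito_max_fraction Maximum tolerated mitochondrial count fraction;
#'   cells strictly above it fail QC.
#' @param min_genes_primary Detected-gene count a cell must strictly exceed to
#'   enter the primary dataset.
#' @param min_genes_secondary Detected-gene count for the secondary dataset
#'   (inclusive).
#' @param prediction_score_min Minimum classifier prediction score; cells below
#'   it are left unassigned.
#' @param rbfox3_min_norm,apoe_max_norm Normalized-expression bounds for the
#'   neuron purification rule: cells with the neuronal marker below
#'   `rbfox3_min_norm` or the glial marker above `apoe_max_norm` are removed.
#' @param pseudobulk_adj_p_max Adjusted-P cutoff (strict) for pseudobulk
#'   differential expression.
#' @param lr_fold_min,lr_pct_min,lr_p_max Ligand-candidate selection: fold
#'   change strictly above `lr_fold_min`, detection fraction strictly above
#'   `lr_pct_min`, raw P strictly below `lr_p_max`.
#' @param n_background_intervals Number of expression-rank intervals used to
#'   stratify background genes.
#' @param genes_per_interval Genes drawn from each interval.
#' @param n_score_replicates Background replicates averaged into one activity
#'   score.
#' @param module_min_genes Minimum surviving genes for a module to be kept.
#' @param n_permutations Label shuffles for the permutation test.
#' @param normalization_scale Library-size target for log-normalization.
#' @param fc_pseudocount Pseudocount added to both group means when forming
#'   fold changes.
#' @param adjust_method Multiple-testing correction, `"BH"` or `"bonferroni"`.
#' @param seed Integer master seed; per-stage streams are derived from it.
#'
#' @return A list of class `ligrec_params`.
#' @examples
#' params <- pipeline_params(lr_fold_min = 2)
#' params$lr_fold_min
#' @export
pipeline_params <- function(mito_max_fraction = 0.20,
                            min_genes_primary = 2000L,
                            min_genes_secondary = 1000L,
                            prediction_score_min = 0.55,
                            rbfox3_min_norm = 0.5,
                            apoe_max_norm = 2.0,
                            pseudobulk_adj_p_max = 1e-20,
                            lr_fold_min = 3.0,
                            lr_pct_min = 0.10,
                            lr_p_max = 0.05,
                            n_background_intervals = 20L,
                            genes_per_interval = 100L,
                            n_score_replicates = 5L,
                            module_min_genes = 10L,
                            n_permutations = 1000L,
                            normalization_scale = 1e4,
                            fc_pseudocount = 1e-9,
                            adjust_method = c("BH", "bonferroni"),
                            seed = 1L) {
  params <- list(
    mito_max_fraction = mito_max_fraction,
    min_genes_primary = as.integer(min_genes_primary),
    min_genes_secondary = as.integer(min_genes_secondary),
    prediction_score_min = prediction_score_min,
    rbfox3_min_norm = rbfox3_min_norm,
    apoe_max_norm = apoe_max_norm,
    pseudobulk_adj_p_max = pseudobulk_adj_p_max,
    lr_fold_min = lr_fold_min,
    lr_pct_min = lr_pct_min,
    lr_p_max = lr_p_max,
    n_background_intervals = as.integer(n_background_intervals),
    genes_per_interval = as.integer(genes_per_interval),
    n_score_replicates = as.integer(n_score_replicates),
    module_min_genes = as.integer(module_min_genes),
    n_permutations = as.integer(n_permutations),
    normalization_scale = normalization_scale,
    fc_pseudocount = fc_pseudocount,
    adjust_method = match.arg(adjust_method),
    seed = as.integer(seed)
  )
  validate_params(params)
  structure(params, class = "ligrec_params")
}

validate_params <- function(p) {
  stopifnot(
    p$mito_max_fraction >= 0, p$mito_max_fraction <= 1,
    p$min_genes_primary > 0, p$min_genes_secondary > 0,
    p$min_genes_secondary <= p$min_genes_primary,
    p$prediction_score_min >= 0, p$prediction_score_min <= 1,
    p$pseudobulk_adj_p_max > 0, p$pseudobulk_adj_p_max <= 1,
    p$lr_fold_min > 0, p$lr_pct_min >= 0, p$lr_pct_min <= 1,
    p$lr_p_max > 0, p$lr_p_max <= 1,
    p$n_background_intervals >= 1, p$genes_per_interval >= 1,
    p$n_score_replicates >= 1, p$module_min_genes >= 1,
    p$n_permutations >= 1, p$normalization_scale > 0,
    p$fc_pseudocount >= 0
  )
  invisible(p)
}

#' Read pipeline parameters from a YAML config file
#'
#' The file holds a flat mapping whose keys match the arguments of
#' [pipeline_params()]; absent keys keep their defaults, unknown keys are an
#' error.
#'
#' @param path Path to a YAML file.
#' @return A `ligrec_params` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(pipeline_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_params, cfg)
}

#' @export
print.ligrec_params <- function(x, ...) {
  cat("<ligrec pipeline parameters>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
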