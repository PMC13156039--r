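#' Filter gene modules against a differentially expressed gene set
#'
#' Each module is intersected with the differentially expressed genes;
#' modules left with fewer than `module_min_genes` (default 10) genes are
#' dropped.
#'
#' @param modules Named list of character vectors (see [read_modules()]).
#' @param de_genes Character vector of differentially expressed genes.
#' @param params A [pipeline_params()].
#' @return Named list of surviving, intersected modules.
#' @export
filter_modules <- function(modules, de_genes, params = pipeline_params()) {
  out <- lapply(modules, function(g) intersect(g, de_genes))
  out[lengths(out) >= params$module_min_genes]
}

#' Per-cell module score, min-max scaled to [0, 1]
#'
#' The raw score of a cell is its mean normalized expression of the module
#' genes minus its mean normalized expression of one stratified background
#' draw (the same expression-binned control machinery as the interactome
#' score, with the module genes as the excluded pool). Raw scores are then
#' scaled as `(raw - min) / (max - min)` across all scored cells; when every
#' raw score is identical the scaled scores are all set to `degenerate`
#' (default 0, i.e. non-activity).
#'
#' @param dataset An [expression_dataset()].
#' @param module Character vector of module genes (must intersect the gene
#'   universe).
#' @param params A [pipeline_params()].
#' @param cells Optional cell ids to score; default all cells.
#' @param degenerate Scaled value used when max = min.
#' @return A tibble of class `module_score_tbl`: `cell_id`, `raw_score`,
#'   `scaled_score`.
#' @export
module_score <- function(dataset, module, params = pipeline_params(),
                         cells = NULL, degenerate = 0) {
  stopifnot(inherits(dataset, "expr_dataset"))
  norm <- get_normalized(dataset)
  module <- intersect(module, rownames(norm))
  if (length(module) == 0) stop("module is empty after gene-universe intersection")
  idx <- if (is.null(cells)) {
    seq_len(ncol(norm))
  } else {
    i <- match(cells, colnames(norm))
    if (anyNA(i)) stop("unknown cell ids in `cells`")
    i
  }
  # background binned by mean expression over the scored cells
  gm <- stats::setNames(
    as.numeric(Matrix::rowMeans(norm[, idx, drop = FALSE])), rownames(norm))
  bg <- stratified_background(dataset, receiver_type = NULL,
                              candidate_pool = module, params = params,
                              gene_means = gm)
  sub <- norm[, idx, drop = FALSE]
  mod_mean <- Matrix::colMeans(sub[module, , drop = FALSE])
  bg_mean <- Matrix::colMeans(sub[as.vector(bg), , drop = FALSE])
  raw <- as.numeric(mod_mean - bg_mean)
  rng <- range(raw)
  scaled <- if (rng[2] > rng[1]) {
    (raw - rng[1]) / (rng[2] - rng[1])
  } else {
    rep(degenerate, length(raw))
  }
  out <- tibble::tibble(cell_id = colnames(sub), raw_score = raw,
                        scaled_score = scaled)
  class(out) <- c("module_score_tbl", class(out))
  out
}

#' Two-group label-permutation test
#'
#' Tests whether two groups of cells differ in a per-cell activity value.
#' The statistic is the absolute difference of group means; the p-value is
#' `(1 + #{permuted >= observed}) / (n_permutations + 1)` over uniform label
#' shuffles, the add-one estimator that can never return zero.
#'
#' @param values Numeric vector, one value per cell.
#' @param labels Two-group assignment (factor, character or logical) of the
#'   same length.
#' @param n_permutations Number of label shuffles (default 1000).
#' @return A list of class `perm_test`: `statistic`, `p_value`,
#'   `n_permutations`, `group_sizes`. Supports [tidy()] and [glance()].
#' @examples
#' set.seed(1)
#' permutation_test(c(0, 0, 0, 10, 10, 10), rep(c("a", "b"), each = 3))
#' @export
permutation_test <- function(values, labels, n_permutations = 1000L) {
  stopifnot(length(values) == length(labels))
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  groups <- unique(labels)
  if (length(groups) != 2) stop("labels must define exactly two groups")
  in_a <- labels == groups[1]
  n_a <- sum(in_a)
  n_b <- sum(!in_a)
  if (n_a == 0 || n_b == 0) stop("both groups must be non-empty")
  observed <- abs(mean(values[in_a]) - mean(values[!in_a]))
  n <- length(values)
  total <- sum(values)
  perm_stat <- vapply(seq_len(n_permutations), function(i) {
    a <- sum(values[sample.int(n, n_a)])
    abs(a / n_a - (total - a) / n_b)
  }, numeric(1))
  p <- (1 + sum(perm_stat >= observed - 1e-12)) / (n_permutations + 1)
  structure(list(statistic = observed, p_value = p,
                 n_permutations = n_permutations,
                 group_sizes = stats::setNames(c(n_a, n_b),
                                               as.character(groups))),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Label-permutation test: |mean difference| = %.4g, p = %.4g (%d shuffles)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_permutations = x$n_permutations)
}

#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_permutations = x$n_permutations,
                 n_group1 = x$group_sizes[[1]], n_group2 = x$group_sizes[[2]])
}
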