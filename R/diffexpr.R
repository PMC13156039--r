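#' Wilcoxon rank-sum test with midranks and an exact small-sample path
#'
#' Computes the rank-sum statistic of `x` (ties resolved by midranks) and a
#' two-sided p-value. For pooled sizes `n + m <= exact_max` (default 12) the
#' p-value is exact: all `choose(n+m, n)` assignments of the pooled midranks
#' are enumerated and the p-value is the probability of a rank-sum deviating
#' from its null mean at least as far as observed. Larger samples use the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Largest pooled size for the enumeration path.
#' @return A list with `statistic` (rank-sum of `x`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  if (n + m <= exact_max) {
    sets <- utils::combn(n + m, n)
    sums <- colSums(matrix(r[sets], nrow = n))
    obs_dev <- abs(w - mu)
    p <- mean(abs(sums - mu) >= obs_dev - 1e-12)
    return(list(statistic = w, p_value = p, method = "exact"))
  }
  N <- n + m
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(statistic = w, p_value = 1, method = "normal"))
  }
  dev <- w - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = w, p_value = p, method = "normal")
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up adjustment (the default) or Bonferroni,
#' order-preserving with the input.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

#' Differential expression of one cell type between two timepoints
#'
#' Compares the cells of `cell_type` at `timepoint` against the same type at
#' the reference timepoint (default day 0, the control). One record per gene
#' detected in either group. Fold change is the ratio of group means on the
#' `expm1`-of-normalized scale with a tiny pseudocount; the p-value is the
#' two-sided Wilcoxon rank-sum test on normalized expression, adjusted
#' within the tested gene set.
#'
#' Passing several types in `cell_type` pools them, which is how the
#' pseudobulk contrast over collapsed neuron types is formed.
#'
#' @param dataset An [expression_dataset()].
#' @param cell_type Cell type name, or a vector of types to pool.
#' @param timepoint Timepoint to test.
#' @param reference_timepoint Control timepoint (default 0).
#' @param params A [pipeline_params()].
#' @return A tibble of class `de_tbl`: `gene`, `cell_type`, `timepoint`,
#'   `fold_change`, `log2_fc`, `pct_expr_group`, `pct_expr_ref`, `p_value`,
#'   `adj_p`. Empty (with a warning) when either group has fewer than 3
#'   cells.
#' @export
de_table <- function(dataset, cell_type, timepoint, reference_timepoint = 0,
                     params = pipeline_params()) {
  stopifnot(inherits(dataset, "expr_dataset"))
  label <- paste(sort(unique(cell_type)), collapse = "+")
  idx_g <- cell_index(dataset, cell_type, timepoint)
  idx_r <- cell_index(dataset, cell_type, reference_timepoint)
  empty <- tibble::tibble(gene = character(), cell_type = character(),
                          timepoint = numeric(), fold_change = numeric(),
                          log2_fc = numeric(), pct_expr_group = numeric(),
                          pct_expr_ref = numeric(), p_value = numeric(),
                          adj_p = numeric())
  class(empty) <- c("de_tbl", class(empty))
  if (length(idx_g) < 3 || length(idx_r) < 3) {
    warning(sprintf("skipping %s at t=%s: fewer than 3 cells in a group",
                    label, format(timepoint)))
    return(empty)
  }
  norm <- get_normalized(dataset)
  cnt_g <- dataset$counts[, idx_g, drop = FALSE]
  cnt_r <- dataset$counts[, idx_r, drop = FALSE]
  detected <- Matrix::rowSums(cnt_g) > 0 | Matrix::rowSums(cnt_r) > 0
  if (!any(detected)) return(empty)
  genes <- rownames(norm)[detected]
  ng <- as.matrix(norm[detected, idx_g, drop = FALSE])
  nr <- as.matrix(norm[detected, idx_r, drop = FALSE])
  pct_g <- Matrix::rowMeans(cnt_g[detected, , drop = FALSE] > 0)
  pct_r <- Matrix::rowMeans(cnt_r[detected, , drop = FALSE] > 0)
  pseudo <- params$fc_pseudocount
  mean_g <- rowMeans(expm1(ng))
  mean_r <- rowMeans(expm1(nr))
  fc <- (mean_g + pseudo) / (mean_r + pseudo)
  p <- vapply(seq_along(genes), function(i) {
    wilcoxon_rank_sum(ng[i, ], nr[i, ])$p_value
  }, numeric(1))
  out <- tibble::tibble(
    gene = genes,
    cell_type = label,
    timepoint = timepoint,
    fold_change = as.numeric(fc),
    log2_fc = log2(fc),
    pct_expr_group = as.numeric(pct_g),
    pct_expr_ref = as.numeric(pct_r),
    p_value = p,
    adj_p = bh_adjust(p, method = params$adjust_method)
  )
  class(out) <- c("de_tbl", class(out))
  out
}

#' Select pseudobulk differentially expressed genes
#'
#' Keeps records whose adjusted P is strictly below the pseudobulk cutoff
#' (default 1e-20).
#'
#' @param records A `de_tbl` from [de_table()].
#' @param params A [pipeline_params()].
#' @return The filtered records.
#' @export
select_pseudobulk_de <- function(records, params = pipeline_params()) {
  out <- dplyr::filter(records, .data$adj_p < params$pseudobulk_adj_p_max)
  class(out) <- unique(c("de_tbl", class(out)))
  out
}

#' Select upregulated ligand-candidate genes
#'
#' The candidate criteria: fold change strictly greater than 3, expression in
#' strictly more than 10% of the cells of the timepoint group, and raw
#' P strictly below 0.05.
#'
#' @param records A `de_tbl` from [de_table()] (possibly several cell types
#'   bound together).
#' @param params A [pipeline_params()].
#' @return The filtered records.
#' @export
select_lr_candidates <- function(records, params = pipeline_params()) {
  out <- dplyr::filter(records,
                       .data$fold_change > params$lr_fold_min,
                       .data$pct_expr_group > params$lr_pct_min,
                       .data$p_value < params$lr_p_max)
  class(out) <- unique(c("de_tbl", class(out)))
  out
}
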