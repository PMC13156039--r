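#' Per-cell quality control
#'
#' Computes the detected-gene count and the mitochondrial count fraction for
#' every cell and applies the discard rules: cells with more than 20% of
#' counts from mitochondrial genes fail outright; the primary dataset keeps
#' cells with strictly more than 2,000 detected genes, the secondary dataset
#' keeps cells with at least 1,000. A gene is "detected" when its count is
#' greater than zero.
#'
#' @param dataset An [expression_dataset()] whose gene table carries
#'   `is_mito` flags.
#' @param params A [pipeline_params()]; thresholds come from
#'   `mito_max_fraction`, `min_genes_primary`, `min_genes_secondary`.
#' @return A tibble of class `qc_tbl` with columns `cell_id`,
#'   `n_genes_detected`, `mito_fraction`, `pass_primary`, `pass_secondary`.
#' @examples
#' sim <- simulate_dataset(simulation_config(n_cell_types = 3,
#'   cells_per_type_per_timepoint = 5, n_genes = 60, timepoints = c(0, 1)))
#' compute_qc(sim$dataset)
#' @export
compute_qc <- function(dataset, params = pipeline_params()) {
  stopifnot(inherits(dataset, "expr_dataset"))
  counts <- dataset$counts
  totals <- Matrix::colSums(counts)
  mito_counts <- Matrix::colSums(counts[dataset$genes$is_mito, , drop = FALSE])
  mito_fraction <- ifelse(totals == 0, 0, mito_counts / totals)
  n_genes <- Matrix::colSums(counts > 0)
  mito_ok <- mito_fraction <= params$mito_max_fraction
  out <- tibble::tibble(
    cell_id = dataset$cells$cell_id,
    n_genes_detected = as.integer(n_genes),
    mito_fraction = as.numeric(mito_fraction),
    pass_primary = unname(mito_ok & n_genes > params$min_genes_primary),
    pass_secondary = unname(mito_ok & n_genes >= params$min_genes_secondary)
  )
  class(out) <- c("qc_tbl", class(out))
  out
}

#' Purify neuron candidates by marker expression
#'
#' Removes putative neurons that look non-neuronal: cells whose normalized
#' expression of the neuronal marker (default `Rbfox3`) is below 0.5, or
#' whose normalized expression of the glial/satellite marker (default
#' `Apoe`) is above 2. The two criteria are applied disjunctively — a cell
#' failing either is removed.
#'
#' @param dataset An [expression_dataset()] (normalized layer is computed on
#'   demand).
#' @param neuron_cells Character vector of candidate neuron cell ids.
#' @param params A [pipeline_params()] supplying `rbfox3_min_norm` and
#'   `apoe_max_norm`.
#' @param neuron_marker,exclusion_marker Gene symbols standing in for the
#'   canonical markers; both must exist in the dataset.
#' @return Character vector: the retained cell ids, in input order.
#' @export
filter_neuron_candidates <- function(dataset, neuron_cells,
                                     params = pipeline_params(),
                                     neuron_marker = "Rbfox3",
                                     exclusion_marker = "Apoe") {
  stopifnot(inherits(dataset, "expr_dataset"))
  norm <- get_normalized(dataset)
  for (marker in c(neuron_marker, exclusion_marker)) {
    if (!marker %in% rownames(norm)) {
      stop("marker gene missing from dataset: ", marker)
    }
  }
  idx <- match(neuron_cells, colnames(norm))
  if (anyNA(idx)) {
    stop("unknown cell ids: ",
         paste(utils::head(neuron_cells[is.na(idx)], 5), collapse = ", "))
  }
  rb <- as.numeric(norm[neuron_marker, idx])
  ap <- as.numeric(norm[exclusion_marker, idx])
  remove <- rb < params$rbfox3_min_norm | ap > params$apoe_max_norm
  neuron_cells[!remove]
}

#' Fit a prototype (nearest-centroid) cell-type classifier
#'
#' A label-transfer classifier with the contract the pipeline needs: a label
#' and a calibrated prediction score per query cell. Per-label centroids are
#' computed in normalized space over the most variable genes of the
#' reference; prediction scores come from a softmax over negative centroid
#' distances, so identical distances give equal scores.
#'
#' @param reference An [expression_dataset()] used as the labelled reference.
#' @param labels Character vector of labels, one per reference cell;
#'   defaults to the reference's `cell_type` column.
#' @param n_top_genes Number of most-variable genes retained.
#' @return An object of class `lr_classifier` (centroid matrix, gene set,
#'   label table); works with [assign_labels()], [tidy()] and [glance()].
#' @export
fit_prototype_classifier <- function(reference, labels = NULL,
                                     n_top_genes = 500L) {
  stopifnot(inherits(reference, "expr_dataset"))
  labels <- labels %||% reference$cells$cell_type
  stopifnot(length(labels) == ncol(reference$counts))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 labels to fit a classifier")
  small <- names(tab)[tab < 3]
  if (length(small) > 0) {
    stop("label(s) with fewer than 3 cells: ", paste(small, collapse = ", "))
  }
  norm <- get_normalized(reference)
  means <- Matrix::rowMeans(norm)
  sq <- Matrix::rowMeans(norm^2)
  vars <- pmax(sq - means^2, 0)
  n_top <- min(as.integer(n_top_genes), nrow(norm))
  top <- rownames(norm)[order(vars, decreasing = TRUE)[seq_len(n_top)]]
  sub <- norm[top, , drop = FALSE]
  centroids <- vapply(sort(unique(labels)), function(lb) {
    Matrix::rowMeans(sub[, labels == lb, drop = FALSE])
  }, numeric(length(top)))
  structure(list(centroids = centroids, genes = top,
                 label_counts = tibble::tibble(label = names(tab),
                                               n_cells = as.integer(tab))),
            class = "lr_classifier")
}

#' Assign labels to query cells with a fitted prototype classifier
#'
#' Prediction scores are the softmax of negative Euclidean distances to the
#' label centroids in normalized space. Cells whose best score falls below
#' `prediction_score_min` (default 0.55) are labelled `"unassigned"`.
#'
#' @param classifier An object from [fit_prototype_classifier()].
#' @param query An [expression_dataset()] sharing the classifier's gene
#'   universe.
#' @param params A [pipeline_params()] supplying `prediction_score_min`.
#' @return A tibble of class `label_tbl`: `cell_id`, `label`,
#'   `prediction_score`.
#' @export
assign_labels <- function(classifier, query, params = pipeline_params()) {
  stopifnot(inherits(classifier, "lr_classifier"),
            inherits(query, "expr_dataset"))
  if (ncol(query$counts) == 0) {
    out <- tibble::tibble(cell_id = character(), label = character(),
                          prediction_score = numeric())
    class(out) <- c("label_tbl", class(out))
    return(out)
  }
  norm <- get_normalized(query)
  missing <- setdiff(classifier$genes, rownames(norm))
  if (length(missing) > 0) {
    stop("query is missing ", length(missing),
         " classifier gene(s), e.g. ", missing[1])
  }
  q <- as.matrix(norm[classifier$genes, , drop = FALSE])
  cent <- classifier$centroids
  # squared distances via the expansion |q - c|^2 = |q|^2 + |c|^2 - 2 q.c
  d2 <- outer(colSums(q^2), colSums(cent^2), "+") - 2 * crossprod(q, cent)
  d <- sqrt(pmax(d2, 0))
  neg <- -d
  neg <- neg - apply(neg, 1, max)
  w <- exp(neg)
  scores <- w / rowSums(w)
  best <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(nrow(scores)), best)]
  label <- colnames(cent)[best]
  label[best_score < params$prediction_score_min] <- "unassigned"
  out <- tibble::tibble(cell_id = query$cells$cell_id, label = label,
                        prediction_score = as.numeric(best_score))
  class(out) <- c("label_tbl", class(out))
  out
}

#' @export
tidy.lr_classifier <- function(x, ...) {
  tibble::tibble(label = colnames(x$centroids),
                 n_genes = length(x$genes),
                 centroid_norm = sqrt(colSums(x$centroids^2)))
}

#' @export
glance.lr_classifier <- function(x, ...) {
  tibble::tibble(n_labels = ncol(x$centroids), n_genes = length(x$genes),
                 n_reference_cells = sum(x$label_counts$n_cells))
}

#' @export
print.lr_classifier <- function(x, ...) {
  cat(sprintf("<prototype classifier> %d labels, %d genes\n",
              ncol(x$centroids), length(x$genes)))
  invisible(x)
}
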