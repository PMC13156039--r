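#' Expression dataset container
#'
#' Holds a sparse gene-by-cell count matrix together with gene and cell
#' metadata and, once computed, a log-normalized layer. Genes are rows and
#' cells are columns, matching the on-disk Matrix Market convention of
#' 10x-style exports.
#'
#' @param counts Sparse (or dense) gene-by-cell matrix of non-negative
#'   integer counts.
#' @param genes Data frame with columns `gene_id`, `gene_symbol`, `is_mito`;
#'   one row per matrix row. Duplicate symbols are disambiguated by suffixing
#'   `.1`, `.2`, ...
#' @param cells Data frame with columns `cell_id`, `cell_type`, `compartment`
#'   (one of `"neuronal"`, `"non_neuronal"`, `"immune"`), `timepoint`,
#'   `condition`; one row per matrix column.
#' @param params Optional [pipeline_params()] used to produce the dataset.
#'
#' @return An object of class `expr_dataset` with elements `counts`,
#'   `normalized` (lazily filled by [log_normalize()]), `genes`, `cells`,
#'   `params`.
#' @examples
#' counts <- matrix(c(0, 3, 1, 0, 5, 2), nrow = 2,
#'                  dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
#' ds <- expression_dataset(
#'   counts,
#'   genes = data.frame(gene_id = c("g1", "g2"), gene_symbol = c("g1", "g2"),
#'                      is_mito = c(FALSE, FALSE)),
#'   cells = data.frame(cell_id = c("c1", "c2", "c3"), cell_type = "t",
#'                      compartment = "immune", timepoint = 0,
#'                      condition = "control"))
#' dim(ds)
#' @export
expression_dataset <- function(counts, genes, cells, params = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  genes <- tibble::as_tibble(genes)
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("gene_id", "gene_symbol", "is_mito") %in% names(genes)))
  stopifnot(all(c("cell_id", "cell_type", "compartment", "timepoint",
                  "condition") %in% names(cells)))
  if (nrow(genes) != nrow(counts)) {
    stop("dimension mismatch: ", nrow(counts), " matrix rows vs ",
         nrow(genes), " gene records")
  }
  if (nrow(cells) != ncol(counts)) {
    stop("dimension mismatch: ", ncol(counts), " matrix columns vs ",
         nrow(cells), " cell records")
  }
  dup <- cells$cell_id[duplicated(cells$cell_id)]
  if (length(dup) > 0) {
    stop("duplicated cell_id: ", paste(unique(dup), collapse = ", "))
  }
  v <- counts@x
  if (any(v < 0)) stop("counts must be non-negative")
  if (any(v != round(v))) stop("counts must be integers")
  genes$gene_symbol <- make.unique(as.character(genes$gene_symbol), sep = ".")
  rownames(counts) <- genes$gene_symbol
  colnames(counts) <- cells$cell_id
  bad <- setdiff(unique(cells$compartment),
                 c("neuronal", "non_neuronal", "immune"))
  if (length(bad) > 0) stop("unknown compartment: ", paste(bad, collapse = ", "))
  structure(list(counts = counts, normalized = NULL, genes = genes,
                 cells = cells, params = params),
            class = "expr_dataset")
}

#' @export
dim.expr_dataset <- function(x) dim(x$counts)

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %d genes x %d cells\n", nrow(x$counts),
              ncol(x$counts)))
  cat(sprintf("  cell types: %s\n",
              paste(sort(unique(x$cells$cell_type)), collapse = ", ")))
  cat(sprintf("  timepoints: %s\n",
              paste(sort(unique(x$cells$timepoint)), collapse = ", ")))
  cat(sprintf("  normalized layer: %s\n",
              if (is.null(x$normalized)) "not computed" else "computed"))
  invisible(x)
}

#' Log-normalize a dataset
#'
#' Per cell, normalized values are `ln(1 + count * scale / cell_total)` with
#' `scale` the library-size target (`normalization_scale`, default 1e4).
#' Cells with zero total counts get an all-zero normalized column and a
#' warning. Zeros stay zeros, so the layer remains sparse.
#'
#' @param dataset An [expression_dataset()].
#' @param scale Library-size target; defaults to the dataset's params or 1e4.
#' @return The dataset with its `normalized` layer filled.
#' @examples
#' ds <- simulate_dataset(simulation_config(n_cell_types = 3,
#'   cells_per_type_per_timepoint = 5, n_genes = 50, timepoints = c(0, 1)))$dataset
#' ds <- log_normalize(ds)
#' @export
log_normalize <- function(dataset, scale = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"))
  scale <- scale %||% (dataset$params$normalization_scale %||% 1e4)
  totals <- Matrix::colSums(dataset$counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts; normalized values set to 0")
  }
  denom <- ifelse(zero, 1, totals)
  norm <- dataset$counts %*% Matrix::Diagonal(x = scale / denom)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(dataset$counts)
  dataset$normalized <- methods::as(norm, "CsparseMatrix")
  dataset
}

# Fetch the normalized layer, computing it lazily.
get_normalized <- function(dataset) {
  if (is.null(dataset$normalized)) dataset <- log_normalize(dataset)
  dataset$normalized
}

# Column indices of the cells of given type(s) and optional timepoint.
cell_index <- function(dataset, cell_type = NULL, timepoint = NULL) {
  keep <- rep(TRUE, nrow(dataset$cells))
  if (!is.null(cell_type)) keep <- keep & dataset$cells$cell_type %in% cell_type
  if (!is.null(timepoint)) keep <- keep & dataset$cells$timepoint %in% timepoint
  which(keep)
}

#' Subset a dataset to a set of cells
#'
#' @param dataset An [expression_dataset()].
#' @param cell_ids Character vector of cell ids to keep.
#' @return The subsetted dataset (normalized layer subset too, if present).
#' @export
subset_cells <- function(dataset, cell_ids) {
  stopifnot(inherits(dataset, "expr_dataset"))
  idx <- match(cell_ids, dataset$cells$cell_id)
  if (anyNA(idx)) {
    stop("unknown cell ids: ",
         paste(utils::head(cell_ids[is.na(idx)], 5), collapse = ", "))
  }
  dataset$counts <- dataset$counts[, idx, drop = FALSE]
  if (!is.null(dataset$normalized)) {
    dataset$normalized <- dataset$normalized[, idx, drop = FALSE]
  }
  dataset$cells <- dataset$cells[idx, , drop = FALSE]
  dataset
}
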