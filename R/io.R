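#' Write a dataset (and optional ground truth) to a fixture directory
#'
#' Emits the standard fixture layout: `matrix.mtx` (Matrix Market, genes x
#' cells, integer counts), `genes.tsv` (`gene_id`, `gene_symbol`, `is_mito`),
#' `cells.tsv` (`cell_id`, `cell_type`, `compartment`, `timepoint`,
#' `condition`) and, when `truth` is given, `truth.json`. [read_dataset()] on
#' the output round-trips counts and metadata exactly.
#'
#' @param dataset An [expression_dataset()].
#' @param directory Output directory (created if missing).
#' @param truth Optional ground-truth list from [simulate_dataset()].
#' @param force Overwrite existing fixture files; without it an existing file
#'   is an error.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(dataset, directory, truth = NULL, force = FALSE) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- file.path(directory, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  if (!is.null(truth)) paths <- c(paths, file.path(directory, "truth.json"))
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0 && !force) {
    stop("refusing to overwrite existing files (use force = TRUE): ",
         paste(basename(existing), collapse = ", "))
  }
  Matrix::writeMM(dataset$counts, paths[1])
  utils::write.table(dataset$genes, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$cells, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth_to_json(truth), file.path(directory, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(paths)
}

truth_to_json <- function(truth) {
  list(
    planted_interactions = truth$planted_interactions,
    module_cell_ids = truth$module_cell_ids,
    module_genes = truth$module_genes,
    composition_table = truth$composition_table,
    de_genes = truth$de_genes
  )
}

#' Read a dataset from a fixture directory
#'
#' Expects the layout written by [write_fixture()]. Malformed metadata rows
#' are rejected with their line numbers; duplicate cell ids, negative or
#' non-integer counts, and dimension mismatches are errors.
#'
#' @param directory Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @param params Optional [pipeline_params()] to attach.
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(directory, params = NULL) {
  need <- file.path(directory, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("missing fixture file(s): ", paste(basename(missing), collapse = ", "))
  }
  counts <- Matrix::readMM(need[1])
  if (length(counts@x) > 0) {
    if (any(counts@x < 0)) stop("matrix.mtx contains negative counts")
    if (any(counts@x != round(counts@x))) {
      stop("matrix.mtx contains non-integer counts")
    }
  }
  genes <- read_tsv_checked(need[2], c("gene_id", "gene_symbol", "is_mito"))
  genes$is_mito <- as.logical(genes$is_mito)
  if (anyNA(genes$is_mito)) stop("genes.tsv: is_mito must be TRUE/FALSE")
  cells <- read_tsv_checked(need[3], c("cell_id", "cell_type", "compartment",
                                       "timepoint", "condition"))
  cells$timepoint <- as.numeric(cells$timepoint)
  if (anyNA(cells$timepoint)) stop("cells.tsv: non-numeric timepoint")
  expression_dataset(counts, genes, cells, params = params)
}

read_tsv_checked <- function(path, columns) {
  lines <- readLines(path)
  if (length(lines) < 1) stop(basename(path), ": empty file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!all(columns %in% header)) {
    stop(basename(path), ": missing column(s) ",
         paste(setdiff(columns, header), collapse = ", "))
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad) > 0) {
    stop(basename(path), ": malformed row(s) at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  tibble::as_tibble(df[, columns, drop = FALSE])
}

#' Read a ligand-receptor reference table
#'
#' The reference is a TSV with columns `ligand`, `receptor`, `targets`
#' (semicolon-separated associated target genes). Duplicate
#' (ligand, receptor) entries and empty target sets are errors.
#'
#' @param path Path to the TSV file.
#' @return A tibble of class `lr_reference` with list-column `targets`.
#' @export
read_lr_reference <- function(path) {
  if (!file.exists(path)) stop("ligand-receptor reference not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = character(0))
  if (!all(c("ligand", "receptor", "targets") %in% names(df))) {
    stop("reference must have columns ligand, receptor, targets")
  }
  lr_reference(df$ligand, df$receptor,
               strsplit(as.character(df$targets), ";", fixed = TRUE))
}

#' Construct a ligand-receptor reference in code
#'
#' @param ligand,receptor Character vectors of equal length.
#' @param targets List of character vectors: the associated target genes
#'   ("gene patterns") of each pair.
#' @return A tibble of class `lr_reference`.
#' @export
lr_reference <- function(ligand, receptor, targets) {
  stopifnot(length(ligand) == length(receptor),
            length(ligand) == length(targets))
  targets <- lapply(targets, function(x) {
    x <- as.character(x)
    unique(x[!is.na(x) & nzchar(x)])
  })
  if (any(lengths(targets) == 0)) {
    stop("every ligand-receptor pair needs a non-empty target set")
  }
  key <- paste(ligand, receptor, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (ligand, receptor) entries: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  out <- tibble::tibble(ligand = as.character(ligand),
                        receptor = as.character(receptor),
                        targets = targets)
  class(out) <- c("lr_reference", class(out))
  out
}

#' Read gene-module definitions
#'
#' Accepts a TSV with columns `module`, `gene` (one row per module-gene) or a
#' JSON object mapping module names to gene arrays.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` file.
#' @return A named list of character vectors.
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) stop("module file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    mods <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(lapply(mods, as.character))
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("module", "gene") %in% names(df))) {
    stop("module TSV must have columns module, gene")
  }
  split(as.character(df$gene), df$module)
}
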