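#' Build sender -> receiver ligand-receptor candidate pairs
#'
#' A pair (sender, receiver, ligand, receptor) is emitted when the ligand is
#' among the sender type's upregulated candidate genes and the receptor is
#' expressed in the receiver type — detected in strictly more than 10% of
#' its cells (at `timepoint`, when given). Self-pairs (sender = receiver)
#' are allowed. Reference entries whose ligand or receptor is absent from
#' the dataset are skipped, with a message reporting how many.
#'
#' @param candidates A `de_tbl` of upregulated genes from
#'   [select_lr_candidates()], covering one or more cell types.
#' @param dataset An [expression_dataset()].
#' @param reference An `lr_reference` (see [lr_reference()]).
#' @param timepoint Timepoint at which receptor expression is assessed;
#'   `NULL` uses all cells of each type.
#' @param params A [pipeline_params()]; the detection threshold is
#'   `lr_pct_min`.
#' @return A tibble with columns `sender`, `receiver`, `ligand`, `receptor`.
#' @export
build_candidate_pairs <- function(candidates, dataset, reference,
                                  timepoint = NULL,
                                  params = pipeline_params()) {
  stopifnot(inherits(dataset, "expr_dataset"))
  up_by_type <- split(candidates$gene, candidates$cell_type)
  genes <- rownames(dataset$counts)
  present <- reference$ligand %in% genes & reference$receptor %in% genes
  if (any(!present)) {
    message(sum(!present),
            " reference pair(s) skipped: ligand or receptor not in dataset")
  }
  ref <- reference[present, , drop = FALSE]
  types <- sort(unique(dataset$cells$cell_type))
  # receptor detection fraction per (gene, receiver type)
  pct_detected <- vapply(types, function(ct) {
    idx <- cell_index(dataset, ct, timepoint)
    if (length(idx) == 0) return(rep(0, nrow(dataset$counts)))
    as.numeric(Matrix::rowMeans(dataset$counts[, idx, drop = FALSE] > 0))
  }, numeric(nrow(dataset$counts)))
  rownames(pct_detected) <- genes
  rows <- list()
  for (i in seq_len(nrow(ref))) {
    lig <- ref$ligand[i]
    rec <- ref$receptor[i]
    senders <- names(up_by_type)[vapply(up_by_type, function(g) lig %in% g,
                                        logical(1))]
    if (length(senders) == 0) next
    receivers <- types[pct_detected[rec, ] > params$lr_pct_min]
    if (length(receivers) == 0) next
    rows[[length(rows) + 1]] <- tidyr::expand_grid(sender = senders,
                                                   receiver = receivers) |>
      dplyr::mutate(ligand = lig, receptor = rec)
  }
  if (length(rows) == 0) {
    return(tibble::tibble(sender = character(), receiver = character(),
                          ligand = character(), receptor = character()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$sender, .data$receiver, .data$ligand, .data$receptor)
}

# Mean normalized expression per gene over the receiver cells at a timepoint.
receiver_gene_means <- function(dataset, receiver_type, timepoint = NULL) {
  idx <- cell_index(dataset, receiver_type, timepoint)
  if (length(idx) == 0) {
    stop("no cells of type ", receiver_type,
         if (!is.null(timepoint)) paste0(" at timepoint ", timepoint))
  }
  norm <- get_normalized(dataset)
  stats::setNames(as.numeric(Matrix::rowMeans(norm[, idx, drop = FALSE])),
                  rownames(norm))
}

#' Draw a stratified background gene matrix
#'
#' Genes outside the candidate pool are ranked by their mean normalized
#' expression in the receiver type's cells, split into
#' `n_background_intervals` equal-rank intervals, and `genes_per_interval`
#' genes are drawn uniformly without replacement from each interval. When
#' the pool of background genes is too small, the per-interval draw is
#' reduced (with a warning), never below 1. The draw consumes the R random
#' stream, so it is deterministic given the seed state.
#'
#' @param dataset An [expression_dataset()].
#' @param receiver_type Cell type whose expression ranks the background.
#' @param candidate_pool Character vector of genes excluded from the
#'   background (the upregulated candidate genes).
#' @param timepoint Timepoint whose receiver cells are used; `NULL` for all.
#' @param params A [pipeline_params()].
#' @param gene_means Optional precomputed vector from an internal caller.
#' @return A character matrix, `n_background_intervals` rows by (possibly
#'   clamped) `genes_per_interval` columns, of background gene symbols.
#' @export
stratified_background <- function(dataset, receiver_type, candidate_pool,
                                  timepoint = NULL,
                                  params = pipeline_params(),
                                  gene_means = NULL) {
  gm <- gene_means %||% receiver_gene_means(dataset, receiver_type, timepoint)
  bg <- setdiff(names(gm), candidate_pool)
  k <- params$n_background_intervals
  if (length(bg) < k) {
    stop("only ", length(bg), " background genes for ", k, " intervals")
  }
  ord <- bg[order(gm[bg], decreasing = TRUE)]
  bins <- split(ord, cut(seq_along(ord), breaks = k, labels = FALSE))
  draw <- min(params$genes_per_interval, min(lengths(bins)))
  if (draw < params$genes_per_interval) {
    warning("background intervals hold only ", draw,
            " gene(s); genes_per_interval reduced from ",
            params$genes_per_interval)
  }
  drawn <- vapply(bins, function(genes) sample(genes, draw), character(draw))
  mat <- t(matrix(drawn, nrow = draw))
  rownames(mat) <- NULL
  mat
}

#' Raw enrichment score of a target-gene program against a background draw
#'
#' The score is the mean, over the receiver type's cells at the timepoint,
#' of the cell's mean normalized expression of the associated genes minus
#' its mean normalized expression of the background matrix genes. By
#' linearity this equals the difference of the two gene-set means of the
#' per-gene averages, which is how it is computed.
#'
#' @param dataset An [expression_dataset()].
#' @param receiver_type,timepoint Receiver cells scored.
#' @param associated_genes The pair's associated target genes.
#' @param background_matrix A draw from [stratified_background()].
#' @param gene_means Optional precomputed per-gene means.
#' @return A single number; may be negative (clipping happens in
#'   [score_interaction()]).
#' @export
enrichment_score <- function(dataset, receiver_type, timepoint,
                             associated_genes, background_matrix,
                             gene_means = NULL) {
  gm <- gene_means %||% receiver_gene_means(dataset, receiver_type, timepoint)
  assoc <- intersect(associated_genes, names(gm))
  if (length(assoc) == 0) {
    stop("no associated genes present in the dataset")
  }
  mean(gm[assoc]) - mean(gm[as.vector(background_matrix)])
}

#' Score one ligand-receptor pair
#'
#' Draws `n_score_replicates` (default 5) independent stratified background
#' matrices, computes the raw enrichment score against each, clips every
#' replicate at zero (negative scores mean non-activity), and averages the
#' clipped replicates into the activity score.
#'
#' @param dataset An [expression_dataset()].
#' @param sender,receiver,ligand,receptor The pair, as produced by
#'   [build_candidate_pairs()].
#' @param timepoint Timepoint scored.
#' @param targets The pair's associated target genes.
#' @param candidate_pool Upregulated genes excluded from the background.
#' @param params A [pipeline_params()].
#' @param gene_means Optional precomputed per-gene receiver means.
#' @return A one-row tibble: the pair, `timepoint`, `activity_score`,
#'   `replicate_scores` (list column of raw, unclipped replicate scores) and
#'   `n_background_genes_used`.
#' @export
score_interaction <- function(dataset, sender, receiver, ligand, receptor,
                              timepoint, targets, candidate_pool,
                              params = pipeline_params(),
                              gene_means = NULL) {
  gm <- gene_means %||% receiver_gene_means(dataset, receiver, timepoint)
  raw <- numeric(params$n_score_replicates)
  n_bg <- 0L
  for (i in seq_len(params$n_score_replicates)) {
    bg <- stratified_background(dataset, receiver, candidate_pool,
                                timepoint = timepoint, params = params,
                                gene_means = gm)
    n_bg <- length(bg)
    raw[i] <- enrichment_score(dataset, receiver, timepoint, targets, bg,
                               gene_means = gm)
  }
  tibble::tibble(sender = sender, receiver = receiver, ligand = ligand,
                 receptor = receptor, timepoint = timepoint,
                 activity_score = mean(pmax(raw, 0)),
                 replicate_scores = list(raw),
                 n_background_genes_used = as.integer(n_bg))
}

#' Score every candidate ligand-receptor pair
#'
#' @param dataset An [expression_dataset()].
#' @param pairs Tibble from [build_candidate_pairs()].
#' @param reference An `lr_reference` supplying each pair's target genes.
#' @param candidate_pool Character vector: the global union of upregulated
#'   genes, excluded from background draws.
#' @param timepoint Timepoint scored.
#' @param params A [pipeline_params()].
#' @return A tibble of class `interactome_tbl`, one row per pair, sorted by
#'   descending activity (ties broken lexicographically).
#' @export
score_interactome <- function(dataset, pairs, reference, candidate_pool,
                              timepoint, params = pipeline_params()) {
  stopifnot(inherits(dataset, "expr_dataset"))
  key <- paste(reference$ligand, reference$receptor, sep = "|")
  rows <- vector("list", nrow(pairs))
  means_cache <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    targets <- reference$targets[[match(paste(p$ligand, p$receptor, sep = "|"),
                                        key)]]
    if (is.null(means_cache[[p$receiver]])) {
      means_cache[[p$receiver]] <- receiver_gene_means(dataset, p$receiver,
                                                       timepoint)
    }
    rows[[i]] <- score_interaction(dataset, p$sender, p$receiver, p$ligand,
                                   p$receptor, timepoint, targets,
                                   candidate_pool, params,
                                   gene_means = means_cache[[p$receiver]])
  }
  out <- if (length(rows) == 0) {
    tibble::tibble(sender = character(), receiver = character(),
                   ligand = character(), receptor = character(),
                   timepoint = numeric(), activity_score = numeric(),
                   replicate_scores = list(),
                   n_background_genes_used = integer())
  } else {
    dplyr::bind_rows(rows)
  }
  out <- interactome_table(out)
  class(out) <- unique(c("interactome_tbl", class(out)))
  out
}

#' Rank an interactome table
#'
#' Sorts activities in descending order, breaking ties by
#' (sender, receiver, ligand, receptor) lexicographic order so output is
#' deterministic.
#'
#' @param activities An interactome tibble.
#' @return The sorted tibble.
#' @export
interactome_table <- function(activities) {
  dplyr::arrange(activities, dplyr::desc(.data$activity_score),
                 .data$sender, .data$receiver, .data$ligand, .data$receptor)
}

#' Export an interactome as a Sankey node/link list
#'
#' Nodes are the cell types appearing as senders or receivers; links are the
#' pairs with strictly positive activity, weighted by the activity score.
#'
#' @param activities An `interactome_tbl`.
#' @return A list with elements `nodes` (tibble: `name`) and `links`
#'   (tibble: `source`, `target`, `ligand`, `receptor`, `weight`).
#' @export
sankey_export <- function(activities) {
  active <- dplyr::filter(interactome_table(activities),
                          .data$activity_score > 0)
  nodes <- tibble::tibble(name = sort(unique(c(activities$sender,
                                               activities$receiver))))
  links <- tibble::tibble(source = active$sender, target = active$receiver,
                          ligand = active$ligand, receptor = active$receptor,
                          weight = active$activity_score)
  list(nodes = nodes, links = links)
}

#' Write a Sankey export to JSON
#'
#' @param sankey A list from [sankey_export()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_sankey_json <- function(sankey, path) {
  jsonlite::write_json(sankey, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
tidy.interactome_tbl <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"replicate_scores")
}

#' @export
glance.interactome_tbl <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x),
                 n_active = sum(x$activity_score > 0),
                 max_activity = if (nrow(x) > 0) max(x$activity_score) else NA_real_)
}
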