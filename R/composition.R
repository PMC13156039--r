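#' Cell-type composition per timepoint within a compartment
#'
#' Counts cells per (timepoint, cell type) and converts them to fractions
#' within the named compartment (`"immune"`, `"neuronal"`,
#' `"non_neuronal"`, or `"all"` for whole-dataset fractions). Fractions at
#' each timepoint sum to 1.
#'
#' @param cells A data frame of cell metadata with columns `cell_id`,
#'   `cell_type`, `compartment`, `timepoint` (e.g. `dataset$cells`, possibly
#'   joined with label assignments).
#' @param compartment Compartment to restrict to.
#' @return A tibble of class `composition_tbl`: `timepoint`, `cell_type`,
#'   `n_cells`, `fraction`.
#' @examples
#' cells <- tibble::tibble(cell_id = as.character(1:6),
#'   cell_type = c("monocyte", "t_cell", "t_cell", "monocyte", "monocyte", "t_cell"),
#'   compartment = "immune", timepoint = c(0, 0, 0, 1, 1, 1))
#' composition_table(cells, "immune")
#' @export
composition_table <- function(cells, compartment = "immune") {
  stopifnot(is.data.frame(cells),
            all(c("cell_type", "compartment", "timepoint") %in% names(cells)))
  timepoints <- sort(unique(cells$timepoint))
  sub <- if (identical(compartment, "all")) {
    cells
  } else {
    dplyr::filter(cells, .data$compartment == !!compartment)
  }
  missing_tp <- setdiff(timepoints, unique(sub$timepoint))
  if (length(missing_tp) > 0) {
    stop("no cells in compartment '", compartment, "' at timepoint(s) ",
         paste(missing_tp, collapse = ", "))
  }
  out <- sub |>
    dplyr::count(.data$timepoint, .data$cell_type, name = "n_cells") |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::mutate(fraction = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup()
  class(out) <- c("composition_tbl", class(out))
  out
}

#' Fold change of a cell type's fraction between two timepoints
#'
#' The ratio of the type's within-compartment fraction at `timepoint` over
#' the reference timepoint, with a 95% confidence interval from the normal
#' approximation on the log ratio, treating the two timepoints' counts as
#' independent binomials.
#'
#' @param table A `composition_tbl` from [composition_table()].
#' @param cell_type Cell type of interest.
#' @param timepoint Timepoint of interest.
#' @param reference_timepoint Baseline timepoint (default 0).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `cell_type`, `timepoint`,
#'   `reference_timepoint`, `fraction`, `reference_fraction`,
#'   `fold_change`, `conf_low`, `conf_high`.
#' @export
composition_fold_change <- function(table, cell_type, timepoint,
                                    reference_timepoint = 0,
                                    conf_level = 0.95) {
  totals <- table |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(n_total = sum(.data$n_cells), .groups = "drop")
  get_row <- function(tp) {
    n_tot <- totals$n_total[totals$timepoint == tp]
    if (length(n_tot) == 0) stop("timepoint not in table: ", tp)
    row <- dplyr::filter(table, .data$timepoint == tp,
                         .data$cell_type == !!cell_type)
    k <- if (nrow(row) == 0) 0L else row$n_cells
    list(k = k, n = n_tot, frac = k / n_tot)
  }
  g <- get_row(timepoint)
  r <- get_row(reference_timepoint)
  if (r$frac == 0) {
    stop("reference fraction is 0 for ", cell_type,
         " at timepoint ", reference_timepoint, "; fold change undefined")
  }
  if (g$frac == 0) {
    stop("fraction is 0 for ", cell_type, " at timepoint ", timepoint,
         "; fold change undefined")
  }
  ratio <- g$frac / r$frac
  se_log <- sqrt((1 - g$frac) / (g$n * g$frac) + (1 - r$frac) / (r$n * r$frac))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(cell_type = cell_type, timepoint = timepoint,
                 reference_timepoint = reference_timepoint,
                 fraction = g$frac, reference_fraction = r$frac,
                 fold_change = ratio,
                 conf_low = exp(log(ratio) - z * se_log),
                 conf_high = exp(log(ratio) + z * se_log))
}
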