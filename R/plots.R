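#' @importFrom ggplot2 autoplot ggplot aes geom_area geom_point geom_line
#'   geom_violin geom_tile labs theme_minimal facet_wrap scale_size_area
NULL

#' Plot cell-type composition over time
#'
#' Stacked-area chart of within-compartment fractions per timepoint.
#'
#' @param object A `composition_tbl` from [composition_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composition_tbl <- function(object, ...) {
  ggplot(object, aes(x = .data$timepoint, y = .data$fraction,
                     fill = .data$cell_type)) +
    geom_area(position = "stack") +
    labs(x = "timepoint (days)", y = "fraction of compartment",
         fill = "cell type") +
    theme_minimal()
}

#' Plot a ligand-receptor interactome as a dot matrix
#'
#' One dot per scored pair, sender vs receiver, sized by activity; pairs
#' with zero activity are dropped.
#'
#' @param object An `interactome_tbl` from [score_interactome()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interactome_tbl <- function(object, ...) {
  active <- object[object$activity_score > 0, , drop = FALSE]
  ggplot(active, aes(x = .data$receiver, y = paste(.data$ligand, .data$receptor,
                                                   sep = " → "),
                     size = .data$activity_score, colour = .data$sender)) +
    geom_point() +
    scale_size_area() +
    labs(x = "receiver cell type", y = "ligand → receptor",
         size = "activity", colour = "sender") +
    theme_minimal()
}

#' Plot the distribution of scaled module scores
#'
#' @param object A `module_score_tbl` from [module_score()].
#' @param groups Optional factor (one per row) to facet or colour by, e.g.
#'   module-carrier status or timepoint.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_score_tbl <- function(object, groups = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (is.null(groups)) {
    ggplot(df, aes(x = "", y = .data$scaled_score)) +
      geom_violin() +
      labs(x = NULL, y = "scaled module score") +
      theme_minimal()
  } else {
    df$group <- groups
    ggplot(df, aes(x = .data$group, y = .data$scaled_score)) +
      geom_violin() +
      labs(x = NULL, y = "scaled module score") +
      theme_minimal()
  }
}

#' Plot QC metrics
#'
#' Detected genes against mitochondrial fraction, coloured by the primary
#' pass flag, with the discard thresholds drawn.
#'
#' @param object A `qc_tbl` from [compute_qc()].
#' @param params The [pipeline_params()] whose thresholds are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_tbl <- function(object, params = pipeline_params(), ...) {
  ggplot(object, aes(x = .data$mito_fraction, y = .data$n_genes_detected,
                     colour = .data$pass_primary)) +
    geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = params$mito_max_fraction,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = params$min_genes_primary,
                        linetype = "dashed") +
    labs(x = "mitochondrial count fraction", y = "detected genes",
         colour = "pass primary") +
    theme_minimal()
}
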