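#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Derive a per-stage child seed from a master seed
#'
#' Stage randomness is isolated by hashing the stage name into an offset, so
#' adding or reordering stages never perturbs the draws of another stage.
#' The result always fits a 32-bit integer.
#'
#' @param master Integer master seed.
#' @param stage Stage name, e.g. `"simulate"`.
#' @return An integer seed.
#' @export
child_seed <- function(master, stage) {
  stopifnot(length(stage) == 1, is.character(stage), nzchar(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (cd in codes) h <- (h * 131 + cd) %% 1000000007
  mixed <- ((as.numeric(master) %% 1000003 + 1) * 2057 + h) %% 2147483647
  as.integer(mixed)
}

# Format numbers with 9 significant digits for reproducible file digests.
fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 9, format = "g"))
}

# Write a data frame as CSV with fixed column order and float formatting.
write_table_fixed <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
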