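#' Write a result table as CSV with a provenance header
#'
#' Writes `#`-prefixed comment lines (package version, timestamp-free
#' provenance fields supplied by the caller) followed by the CSV body, so the
#' file stays spreadsheet-safe and greppable while recording how it was made.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param provenance Named character vector or list of provenance fields
#'   (e.g. the command parameters and the seed).
#' @return `path`, invisibly.
#' @export
write_rm_table <- function(x, path, provenance = NULL) {
  header <- c(
    sprintf("# rmdyn %s", as.character(utils::packageVersion("rmdyn"))),
    if (length(provenance)) {
      sprintf("# %s: %s", names(provenance),
              vapply(provenance, function(v) paste(format(v), collapse = " "),
                     character(1)))
    }
  )
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a result table written by [write_rm_table()]
#'
#' @param path File path.
#' @param required_cols Optional character vector of column names that must
#'   be present; a schema error lists what is expected otherwise.
#' @return A tibble.
#' @export
read_rm_table <- function(path, required_cols = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(out) == 0 && ncol(out) == 0) {
    abort(sprintf("Empty dataset: %s", path))
  }
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(out))
    if (length(missing)) {
      abort(sprintf("Schema error in %s: missing columns %s (expected %s).",
                    path, paste(missing, collapse = ", "),
                    paste(required_cols, collapse = ", ")))
    }
  }
  out
}
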