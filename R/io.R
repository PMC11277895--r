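#' Read a delimited omics table in DepMap portal layout
#'
#' Reads a CSV/TSV export with one identifier column (or row, for
#' samples-in-columns orientation) and numeric cells. Empty cells and the
#' strings `NA`/`NaN` (and any other non-numeric cell) become missing
#' entries. The delimiter is taken from the file extension: `.csv` is
#' comma-separated, anything else tab-separated.
#'
#' @param path Path to the delimited file.
#' @param view_kind View kind passed to [omics_matrix()].
#' @param orientation `"samples_in_rows"` (default; first column = sample id)
#'   or `"samples_in_columns"` (first column = feature id); the returned
#'   object is always samples-in-rows.
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, view_kind,
                              orientation = c("samples_in_rows", "samples_in_columns")) {
  orientation <- match.arg(orientation)
  m <- read_id_table(path)
  if (orientation == "samples_in_columns") m <- t(m)
  omics_matrix(m, view_kind = view_kind)
}

#' Read a samples x drugs log(IC50) table
#'
#' @inheritParams read_omics_matrix
#' @return A [response_matrix()].
#' @export
read_response_matrix <- function(path,
                                 orientation = c("samples_in_rows", "samples_in_columns")) {
  orientation <- match.arg(orientation)
  m <- read_id_table(path)
  if (orientation == "samples_in_columns") m <- t(m)
  response_matrix(m)
}

# internal: delimited table -> numeric matrix with rownames from column 1.
# Non-numeric cells (including "", "NA", "NaN") become NA.
read_id_table <- function(path) {
  if (!file.exists(path)) abort_modra("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort_modra("table in %s has no data columns", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) abort_modra("duplicate ids in %s", path)
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  dimnames(num) <- list(ids, colnames(df)[-1L])
  if (nrow(num) == 0L || ncol(num) == 0L) abort_modra("table in %s is empty", path)
  num
}

#' Write a multi-omics dataset as one CSV per view plus a response CSV
#'
#' Produces the same samples-in-rows layout [read_omics_matrix()] reads:
#' `mutation.csv`, `cnv.csv`, `methylation.csv`, `expression.csv`,
#' `response.csv`. Missing entries are written as empty cells.
#'
#' @param data A [multiomics_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_multiomics_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in data$views) {
    write_id_table(v$values, file.path(dir, paste0(v$view_kind, ".csv")))
  }
  write_id_table(data$response$values, file.path(dir, "response.csv"))
  invisible(dir)
}

write_id_table <- function(values, path) {
  df <- data.frame(sample_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Read a directory written by [write_multiomics_dataset()]
#'
#' @param dir Directory containing the five CSV files.
#' @return A [multiomics_dataset()].
#' @export
read_multiomics_dataset <- function(dir) {
  views <- lapply(omics_view_kinds(), function(k) {
    read_omics_matrix(file.path(dir, paste0(k, ".csv")), view_kind = k)
  })
  response <- read_response_matrix(file.path(dir, "response.csv"))
  multiomics_dataset(views, response)
}
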