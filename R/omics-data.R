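#' Omics view containers
#'
#' An `omics_matrix` holds one molecular view as a samples x features numeric
#' matrix together with a logical missingness mask of the same shape
#' (`TRUE` = missing). Sample and feature identifiers live in the matrix
#' dimnames and must be unique. The view kind constrains the admissible
#' non-missing values: mutation calls are 0/1, methylation fractions lie in
#' \[0, 1\]; copy number is integer-valued and expression nonnegative (the
#' latter two are not enforced, matching upstream export variability).
#'
#' @param values Numeric samples x features matrix. `NA` entries are taken as
#'   missing when `missing_mask` is not supplied.
#' @param view_kind One of `"mutation"`, `"cnv"`, `"methylation"`,
#'   `"expression"`.
#' @param sample_ids,feature_ids Optional character identifiers; default to
#'   the dimnames of `values`.
#' @param missing_mask Optional logical matrix, same shape as `values`.
#' @param strict When `TRUE` (default) mutation values must be exactly 0/1;
#'   internal reconstructions after mean imputation pass `FALSE`, which only
#'   requires mutation values to stay within \[0, 1\] (imputed means are
#'   fractional and deliberately not re-binarized).
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, view_kind, sample_ids = rownames(values),
                         feature_ids = colnames(values), missing_mask = NULL,
                         strict = TRUE) {
  view_kind <- match.arg(view_kind, omics_view_kinds())
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_modra("`values` must be a numeric matrix")
  }
  if (nrow(values) == 0L) abort_modra("omics matrix has zero samples")
  if (ncol(values) == 0L) abort_modra("omics matrix has zero features")
  if (is.null(sample_ids) || is.null(feature_ids)) {
    abort_modra("sample and feature identifiers are required")
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values)) {
    abort_modra("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) abort_modra("duplicate sample ids in %s view", view_kind)
  if (anyDuplicated(feature_ids)) abort_modra("duplicate feature ids in %s view", view_kind)
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  if (!is.logical(missing_mask) || !identical(dim(missing_mask), dim(values))) {
    abort_modra("`missing_mask` must be a logical matrix with the shape of `values`")
  }
  values[missing_mask] <- NA_real_
  dimnames(values) <- list(sample_ids, feature_ids)
  dimnames(missing_mask) <- dimnames(values)
  obs <- values[!missing_mask]
  if (view_kind == "mutation" && length(obs)) {
    ok <- if (strict) all(obs %in% c(0, 1)) else all(obs >= 0 & obs <= 1)
    if (!ok) abort_modra("mutation view contains non-binary values")
  }
  if (view_kind == "methylation" && length(obs) && (any(obs < 0) || any(obs > 1))) {
    abort_modra("methylation view contains values outside [0, 1]")
  }
  structure(
    list(values = values, view_kind = view_kind, missing_mask = missing_mask),
    class = "omics_matrix"
  )
}

omics_view_kinds <- function() c("mutation", "cnv", "methylation", "expression")

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix> %s: %d samples x %d features (%.1f%% missing)\n",
    x$view_kind, nrow(x$values), ncol(x$values), 100 * mean(x$missing_mask)
  ))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Sample, feature and drug identifier accessors
#'
#' @param x An [omics_matrix()], [response_matrix()] or
#'   [multiomics_dataset()].
#' @return A character vector of identifiers.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.omics_matrix <- function(x) rownames(x$values)
#' @export
sample_ids.response_matrix <- function(x) rownames(x$values)
#' @export
sample_ids.multiomics_dataset <- function(x) rownames(x$response$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(x) colnames(x$values)

#' Drug-response container
#'
#' Samples x drugs matrix of log(IC50) values with a missingness mask.
#' Lower values mean a more sensitive (more effective) response.
#'
#' @param values Numeric samples x drugs matrix; `NA` = missing response.
#' @param sample_ids,drug_ids Optional identifiers; default to dimnames.
#' @param missing_mask Optional logical matrix.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(values, sample_ids = rownames(values),
                            drug_ids = colnames(values), missing_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_modra("`values` must be a numeric matrix")
  }
  if (ncol(values) < 1L) abort_modra("response matrix needs at least one drug")
  sample_ids <- as.character(sample_ids)
  drug_ids <- as.character(drug_ids)
  if (anyDuplicated(sample_ids)) abort_modra("duplicate sample ids in response matrix")
  if (anyDuplicated(drug_ids)) abort_modra("duplicate drug ids in response matrix")
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  values[missing_mask] <- NA_real_
  dimnames(values) <- list(sample_ids, drug_ids)
  dimnames(missing_mask) <- dimnames(values)
  structure(
    list(values = values, missing_mask = missing_mask),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf(
    "<response_matrix> %d samples x %d drugs (%.1f%% missing)\n",
    nrow(x$values), ncol(x$values), 100 * mean(x$missing_mask)
  ))
  invisible(x)
}

#' Bundle four sample-aligned omics views with a response matrix
#'
#' All four views and the response matrix must carry identical sample ids in
#' identical order. View values may still contain missing entries (e.g. the
#' raw output of [generate_dataset()] with a nonzero missing rate); the
#' preprocessing pipeline [preprocess_multiomics()] guarantees completeness.
#'
#' @param views List of four [omics_matrix()] objects, one per view kind.
#' @param response A [response_matrix()].
#' @return An object of class `multiomics_dataset`.
#' @export
multiomics_dataset <- function(views, response) {
  if (length(views) != 4L) abort_modra("a multiomics dataset has exactly 4 views")
  if (!all(vapply(views, inherits, logical(1), "omics_matrix"))) {
    abort_modra("all views must be omics_matrix objects")
  }
  if (!inherits(response, "response_matrix")) {
    abort_modra("`response` must be a response_matrix")
  }
  ids <- sample_ids(response)
  for (v in views) {
    if (!identical(sample_ids(v), ids)) {
      abort_modra("sample ids of the %s view do not match the response matrix", v$view_kind)
    }
  }
  names(views) <- vapply(views, `[[`, character(1), "view_kind")
  if (anyDuplicated(names(views))) abort_modra("duplicate view kinds")
  structure(list(views = views, response = response), class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf(
    "<multiomics_dataset> %d samples, %d drugs\n",
    length(sample_ids(x)), length(drug_ids(x))
  ))
  for (v in x$views) {
    cat(sprintf(
      "  %-12s %5d features (%.1f%% missing)\n",
      v$view_kind, ncol(v$values), 100 * mean(v$missing_mask)
    ))
  }
  invisible(x)
}

#' @rdname sample_ids
#' @export
drug_ids <- function(x) {
  if (inherits(x, "multiomics_dataset")) colnames(x$response$values) else colnames(x$values)
}

n_samples <- function(x) length(sample_ids(x))

# internal: subset every matrix of a dataset to the given sample indices/ids
subset_dataset <- function(data, idx) {
  views <- lapply(data$views, function(v) {
    omics_matrix(v$values[idx, , drop = FALSE], v$view_kind,
                 missing_mask = v$missing_mask[idx, , drop = FALSE],
                 strict = FALSE)
  })
  resp <- response_matrix(data$response$values[idx, , drop = FALSE],
                          missing_mask = data$response$missing_mask[idx, , drop = FALSE])
  multiomics_dataset(views, resp)
}
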