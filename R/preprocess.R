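#' Drop samples with excessive missingness
#'
#' Keeps exactly the samples whose fraction of missing entries (over the
#' view's features) is at most `threshold`; a sample is dropped only when its
#' missing fraction strictly exceeds the threshold. Sample order is
#' preserved. The default 0.30 reflects the usual "more than 30% missing"
#' exclusion rule for omics exports.
#'
#' @param m An [omics_matrix()].
#' @param threshold Maximum tolerated missing fraction in \[0, 1\].
#' @return The filtered [omics_matrix()].
#' @export
filter_samples_by_missingness <- function(m, threshold = 0.30) {
  stopifnot(inherits(m, "omics_matrix"))
  if (threshold < 0 || threshold > 1) abort_modra("`threshold` must lie in [0, 1]")
  frac <- rowMeans(m$missing_mask)
  keep <- frac <= threshold
  if (!any(keep)) abort_modra("all samples exceed the missingness threshold")
  omics_matrix(m$values[keep, , drop = FALSE], m$view_kind,
               missing_mask = m$missing_mask[keep, , drop = FALSE],
               strict = FALSE)
}

#' Remove features whose every observed value is zero
#'
#' A feature (gene) is removed when all of its non-missing values are 0;
#' features with no observed values at all are likewise removed (nothing
#' observed distinguishes them from zero). Feature order is preserved.
#'
#' @param m An [omics_matrix()].
#' @return The filtered [omics_matrix()].
#' @export
drop_all_zero_genes <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  observed_nonzero <- colSums(!m$missing_mask & m$values != 0, na.rm = TRUE)
  keep <- observed_nonzero > 0
  if (!any(keep)) abort_modra("all features are all-zero")
  omics_matrix(m$values[, keep, drop = FALSE], m$view_kind,
               missing_mask = m$missing_mask[, keep, drop = FALSE],
               strict = FALSE)
}

#' Impute missing entries with the per-feature mean
#'
#' Each missing cell is replaced by the mean of the feature's observed
#' values, so per-feature means are unchanged. Errors if a feature has no
#' observed value to average.
#'
#' @param m An [omics_matrix()].
#' @return A complete [omics_matrix()] (all-false missing mask).
#' @export
impute_mean <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  n_obs <- colSums(!m$missing_mask)
  if (any(n_obs == 0L)) {
    abort_modra("feature(s) entirely missing, cannot impute: %s",
                paste(feature_ids(m)[n_obs == 0L], collapse = ", "))
  }
  vals <- m$values
  mu <- colMeans(vals, na.rm = TRUE)
  idx <- which(m$missing_mask, arr.ind = TRUE)
  if (nrow(idx)) vals[idx] <- mu[idx[, 2L]]
  mask <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  omics_matrix(vals, m$view_kind, missing_mask = mask, strict = FALSE)
}

#' Restrict views and responses to their shared samples
#'
#' Intersects the sample ids of all four views and the response matrix and
#' reorders every matrix to that intersection in lexicographic id order, the
#' deterministic convention used throughout.
#'
#' @param views List of four [omics_matrix()] objects.
#' @param response A [response_matrix()].
#' @return A [multiomics_dataset()].
#' @export
align_samples <- function(views, response) {
  id_sets <- c(lapply(views, sample_ids), list(sample_ids(response)))
  shared <- Reduce(intersect, id_sets)
  if (length(shared) == 0L) abort_modra("no samples shared across all inputs")
  shared <- sort(shared)
  views <- lapply(views, function(v) {
    omics_matrix(v$values[shared, , drop = FALSE], v$view_kind,
                 missing_mask = v$missing_mask[shared, , drop = FALSE],
                 strict = FALSE)
  })
  response <- response_matrix(response$values[shared, , drop = FALSE],
                              missing_mask = response$missing_mask[shared, , drop = FALSE])
  multiomics_dataset(views, response)
}

#' Full preprocessing pipeline for raw omics views
#'
#' Applies, per view, the missingness filter, all-zero gene removal and mean
#' imputation, then aligns all views and the response matrix on their shared
#' samples. The returned dataset has no missing view entries. A step-by-step
#' log of sample/feature counts is attached for provenance.
#'
#' @param views List of four raw [omics_matrix()] objects.
#' @param response A [response_matrix()].
#' @param max_missing Per-sample missing-fraction threshold (default 0.30).
#' @return A list with elements `dataset` (the [multiomics_dataset()]) and
#'   `log` (a tibble with one row per view and step, recording sample and
#'   feature counts).
#' @export
preprocess_multiomics <- function(views, response, max_missing = 0.30) {
  steps <- list()
  record <- function(view, step, m) {
    tibble::tibble(view = view, step = step,
                   n_samples = nrow(m$values), n_features = ncol(m$values))
  }
  processed <- lapply(views, function(v) {
    steps[[length(steps) + 1L]] <<- record(v$view_kind, "input", v)
    v <- filter_samples_by_missingness(v, max_missing)
    steps[[length(steps) + 1L]] <<- record(v$view_kind, "missingness_filter", v)
    v <- drop_all_zero_genes(v)
    steps[[length(steps) + 1L]] <<- record(v$view_kind, "drop_all_zero", v)
    v <- impute_mean(v)
    steps[[length(steps) + 1L]] <<- record(v$view_kind, "impute_mean", v)
    v
  })
  data <- align_samples(processed, response)
  for (v in data$views) {
    steps[[length(steps) + 1L]] <- record(v$view_kind, "align_samples", v)
    stopifnot(!any(v$missing_mask))
  }
  list(dataset = data, log = dplyr::bind_rows(steps))
}
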