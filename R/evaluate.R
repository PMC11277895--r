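#' Mean squared error over observed entries
#'
#' @param pred,y Numeric matrices (or vectors) of identical shape.
#' @param mask Optional logical matrix, `TRUE` = missing (excluded from sum
#'   and count).
#' @return Nonnegative scalar.
#' @export
compute_mse <- function(pred, y, mask = NULL) {
  if (!identical(dim(pred), dim(y)) || length(pred) != length(y)) {
    abort_modra("prediction/response shapes differ")
  }
  keep <- if (is.null(mask)) rep(TRUE, length(y)) else !mask
  if (!any(keep)) abort_modra("no observed entries")
  mean(((pred - y)[keep])^2)
}

#' Absolute deviation between two predicted responses
#'
#' Small helper used in case-study reporting, e.g. comparing the base and
#' full models' predicted response for one sample-drug pair.
#'
#' @param a,b Numeric scalars or vectors.
#' @return `abs(a - b)`.
#' @export
response_deviation <- function(a, b) abs(a - b)

#' Binarize responses against the training-fold median
#'
#' Label 1 ("sensitive") iff the value is strictly below the median of the
#' training-fold responses for that drug; values at or above the median
#' (including exact ties) are labelled 0 ("resistant").
#'
#' @param train_values Non-empty numeric training responses for one drug
#'   (NA dropped).
#' @param values Values to binarize.
#' @return Integer vector of 0/1 labels.
#' @export
binarize_by_train_median <- function(train_values, values) {
  train_values <- train_values[!is.na(train_values)]
  if (length(train_values) == 0L) abort_modra("no training responses to take a median of")
  as.integer(values < stats::median(train_values))
}

# midrank Mann-Whitney AUROC; NA when truth has a single class
auroc_score <- function(truth, scores) {
  pos <- truth == 1L
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # midranks handle score ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

f1_score <- function(truth, predicted) {
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 0L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' F1 and AUROC for one drug
#'
#' F1 compares binary truth with binary predictions; AUROC ranks the
#' continuous scores (higher score = predicted more sensitive) against the
#' truth with the midrank Mann-Whitney formula. AUROC is `NA` when the
#' truth contains a single class.
#'
#' @param truth Integer 0/1 labels (1 = sensitive).
#' @param predicted Optional integer 0/1 predicted labels (for F1).
#' @param scores Optional numeric scores (for AUROC); by convention the
#'   negated predicted concentration, since lower log(IC50) means more
#'   sensitive.
#' @return A tibble with columns `f1` and `auroc`.
#' @export
classification_metrics <- function(truth, predicted = NULL, scores = NULL) {
  truth <- as.integer(truth)
  tibble::tibble(
    f1 = if (is.null(predicted)) NA_real_ else f1_score(truth, as.integer(predicted)),
    auroc = if (is.null(scores)) NA_real_ else auroc_score(truth, scores)
  )
}

#' Per-drug MSE ranking table
#'
#' One row per drug, sorted by ascending MSE with drug id as the
#' deterministic tiebreak.
#'
#' @param pred,y Samples x drugs matrices.
#' @param mask Optional logical missingness matrix (`TRUE` = missing).
#' @param drug_ids Drug identifiers; default from `y`'s column names.
#' @return A tibble with `drug_id`, `mse`, `n_observed`, ranked ascending.
#' @export
per_drug_mse_table <- function(pred, y, mask = NULL, drug_ids = colnames(y)) {
  if (!identical(dim(pred), dim(y))) abort_modra("prediction/response shapes differ")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(y), ncol(y))
  if (is.null(drug_ids)) drug_ids <- sprintf("drug_%02d", seq_len(ncol(y)))
  rows <- lapply(seq_len(ncol(y)), function(d) {
    keep <- !mask[, d]
    tibble::tibble(
      drug_id = drug_ids[d],
      mse = if (any(keep)) mean((pred[keep, d] - y[keep, d])^2) else NA_real_,
      n_observed = sum(keep)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$mse, .data$drug_id)
}

#' Full metrics report for a prediction matrix
#'
#' Computes the overall masked MSE plus, per drug, MSE, F1 and AUROC after
#' median-threshold binarization: both the observed and the predicted
#' responses are binarized against the per-drug median of the *training*
#' responses, and the AUROC score is the negated predicted concentration.
#' Aggregate F1/AUROC are macro-averages over drugs by default (drugs whose
#' held-out truth is single-class are excluded from the AUROC aggregate);
#' `pooled = TRUE` instead pools all drug-sample pairs.
#'
#' @param pred Samples x drugs predicted responses.
#' @param y,mask Observed responses and missingness (`TRUE` = missing).
#' @param train_y,train_mask Training-fold responses used for the per-drug
#'   median thresholds.
#' @param pooled Pool drug-sample pairs instead of macro-averaging.
#' @return A `modra_metrics` list: scalars `mse`, `f1`, `auroc` and the
#'   `per_drug` tibble (drug_id, threshold, mse, f1, auroc).
#' @export
metrics_report <- function(pred, y, mask = NULL, train_y, train_mask = NULL,
                           pooled = FALSE) {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(y), ncol(y))
  if (is.null(train_mask)) train_mask <- matrix(FALSE, nrow(train_y), ncol(train_y))
  D <- ncol(y)
  ids <- colnames(y)
  if (is.null(ids)) ids <- sprintf("drug_%02d", seq_len(D))
  rows <- vector("list", D)
  pool_truth <- pool_pred <- pool_scores <- list()
  for (d in seq_len(D)) {
    tr <- train_y[!train_mask[, d], d]
    thr <- stats::median(tr)
    keep <- !mask[, d]
    yt <- y[keep, d]
    pt <- pred[keep, d]
    truth <- binarize_by_train_median(tr, yt)
    plab <- binarize_by_train_median(tr, pt)
    cm <- classification_metrics(truth, plab, scores = -pt)
    rows[[d]] <- tibble::tibble(
      drug_id = ids[d], threshold = thr,
      mse = if (length(yt)) mean((pt - yt)^2) else NA_real_,
      f1 = cm$f1, auroc = cm$auroc
    )
    pool_truth[[d]] <- truth
    pool_pred[[d]] <- plab
    pool_scores[[d]] <- -pt
  }
  per_drug <- dplyr::bind_rows(rows)
  if (pooled) {
    cm <- classification_metrics(unlist(pool_truth), unlist(pool_pred),
                                 unlist(pool_scores))
    f1 <- cm$f1
    auroc <- cm$auroc
  } else {
    f1 <- mean(per_drug$f1, na.rm = TRUE)
    auroc <- mean(per_drug$auroc, na.rm = TRUE)
  }
  structure(list(
    mse = compute_mse(pred, y, mask), f1 = f1, auroc = auroc,
    per_drug = per_drug, pooled = pooled
  ), class = "modra_metrics")
}

#' @export
print.modra_metrics <- function(x, ...) {
  cat(sprintf("<modra_metrics> MSE %.4f, F1 %.4f, AUROC %.4f (%s)\n",
              x$mse, x$f1, x$auroc,
              if (x$pooled) "pooled" else "macro over drugs"))
  invisible(x)
}

#' Held-out coefficient of determination
#'
#' `1 - sum((pred - y)^2) / sum((y - mean(y))^2)` over observed entries.
#'
#' @inheritParams compute_mse
#' @return Scalar R-squared (can be negative for a worse-than-mean model).
#' @export
heldout_r2 <- function(pred, y, mask = NULL) {
  keep <- if (is.null(mask)) rep(TRUE, length(y)) else !mask
  yy <- y[keep]
  pp <- pred[keep]
  1 - sum((pp - yy)^2) / sum((yy - mean(yy))^2)
}

#' Within-batch cross-view retrieval accuracy
#'
#' Measures how well the latent spaces are aligned: samples are split into
#' batches, each batch's four embeddings are computed, and for every
#' ordered view pair (i != j) and every sample the retrieval is a success
#' when the sample's own column maximises its row of the cross-view
#' similarity matrix. Chance level is 1/batch size.
#'
#' @param fit A `modra_fit`.
#' @param data A complete [multiomics_dataset()].
#' @param batch_size Batch size for the evaluation (default: training batch
#'   size).
#' @param seed Seed for the batch shuffle.
#' @return Overall top-1 accuracy (scalar) with per-pair detail in
#'   attribute `"per_pair"`.
#' @export
cross_view_retrieval <- function(fit, data, batch_size = NULL, seed = 0L) {
  if (is.null(batch_size)) batch_size <- fit$train_config$batch_size
  tensors <- dataset_tensors(data, fit$train_config$views_enabled)
  tensors$x <- apply_normalizer(tensors$x, fit$normalizer)
  n <- n_samples(data)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  order <- sample(n)
  starts <- seq(1L, n, by = batch_size)
  hits <- matrix(0, 4L, 4L)
  trials <- matrix(0, 4L, 4L)
  for (s in starts) {
    idx <- order[s:min(s + batch_size - 1L, n)]
    if (length(idx) < 2L) next
    x <- lapply(tensors$x, function(m) m[, idx, drop = FALSE])
    z <- lapply(seq_along(x), function(i) {
      feature_extract(x[[i]], fit$params$extractor[[i]])
    })
    for (i in 1:4) {
      for (j in 1:4) {
        if (i == j) next
        S <- sample_similarity(z[[i]], z[[j]])
        top <- apply(S, 1L, which.max)
        hits[i, j] <- hits[i, j] + sum(top == seq_along(idx))
        trials[i, j] <- trials[i, j] + length(idx)
      }
    }
  }
  acc <- sum(hits) / sum(trials)
  per_pair <- hits / pmax(trials, 1)
  attr(acc, "per_pair") <- per_pair
  acc
}
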