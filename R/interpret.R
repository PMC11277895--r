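#' Omics-masking importance analysis
#'
#' Establishes baseline per-drug prediction error, then repeats prediction
#' with each view's input zeroed in turn. The reported delta is
#' `masked MSE - baseline MSE`: positive delta means masking the view made
#' predictions worse, i.e. the view contributed useful information;
#' negative delta means the view was (for that drug) detrimental.
#'
#' @param fit A trained `modra_fit`.
#' @param data A complete [multiomics_dataset()].
#' @param sample_idx Samples to evaluate (default all).
#' @return A `modra_importance` tibble with one row per (drug, view):
#'   `drug_id`, `view`, `baseline_mse`, `masked_mse`, `delta`.
#' @export
omics_mask_importance <- function(fit, data, sample_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- seq_len(n_samples(data))
  y <- data$response$values[sample_idx, , drop = FALSE]
  mask <- data$response$missing_mask[sample_idx, , drop = FALSE]
  base_pred <- predict(fit, data, sample_idx = sample_idx)
  base_tbl <- per_drug_mse_table(base_pred, y, mask, fit$drug_ids) |>
    dplyr::select(drug_id = "drug_id", baseline_mse = "mse")
  rows <- lapply(seq_along(data$views), function(v) {
    mp <- predict(fit, data, sample_idx = sample_idx, masked_view = v)
    per_drug_mse_table(mp, y, mask, fit$drug_ids) |>
      dplyr::select(drug_id = "drug_id", masked_mse = "mse") |>
      dplyr::mutate(view = names(data$views)[v])
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::left_join(base_tbl, by = "drug_id") |>
    dplyr::mutate(delta = .data$masked_mse - .data$baseline_mse) |>
    dplyr::select("drug_id", "view", "baseline_mse", "masked_mse", "delta") |>
    dplyr::arrange(.data$drug_id, .data$view)
  class(out) <- c("modra_importance", class(out))
  out
}

# gradient of Pred[drug, 1] wrt the four input vectors, single-sample batch
input_gradient <- function(fit, x_list, drug_index) {
  cfg <- fit$model_config
  fw <- model_forward(x_list, fit$params, cfg, training = FALSE,
                      use_attention = fit$train_config$use_attention,
                      compute_alignment = FALSE)
  dpred <- matrix(0, nrow(fw$pred), ncol(fw$pred))
  dpred[drug_index, 1L] <- 1
  pb <- predictor_backward(dpred, fw$cache$predictor, fit$params$predictor)
  d2 <- cfg$d2
  if (fit$train_config$use_attention) {
    ab <- coattention_backward(pb$dZp, fw$cache$attention,
                               fit$params$attention, cfg)
    dz <- ab$dz
  } else {
    dz <- lapply(seq_along(x_list), function(i) {
      pb$dZp[((i - 1L) * d2 + 1L):(i * d2), , drop = FALSE]
    })
  }
  lapply(seq_along(x_list), function(i) {
    extractor_backward(dz[[i]], fw$cache$extract[[i]],
                       fit$params$extractor[[i]])$dx
  })
}

#' Per-gene attribution for one sample and drug
#'
#' Scores every input gene of every view for its contribution to the
#' predicted response of one drug in one sample. Two standard attribution
#' methods are offered (how the original analysis scored "contribution" is
#' not documented, so the method used is always recorded in the output):
#'
#' * `grad_x_input`: `|dPred/dx_g * x_g|` (saliency times input),
#' * `occlusion`: `|Pred - Pred with gene g zeroed|`.
#'
#' Both operate on the network's input representation (the sample's view
#' vectors after the fit's stored normalisation, when the model was trained
#' with `normalize_inputs`). Scores are comparable across views because all
#' genes enter one ranking.
#'
#' @param fit A trained `modra_fit`.
#' @param data A complete [multiomics_dataset()].
#' @param sample_id Sample identifier (or integer index).
#' @param drug Drug identifier (or integer index).
#' @param method `"grad_x_input"` (default) or `"occlusion"`.
#' @return A `modra_attribution` tibble: `gene_id`, `view`, `score`,
#'   descending by score, with the method and indices in attributes.
#' @export
gene_attribution <- function(fit, data, sample_id, drug,
                             method = c("grad_x_input", "occlusion")) {
  method <- match.arg(method)
  s_idx <- if (is.character(sample_id)) match(sample_id, sample_ids(data)) else sample_id
  d_idx <- if (is.character(drug)) match(drug, fit$drug_ids) else drug
  if (is.na(s_idx) || s_idx < 1 || s_idx > n_samples(data)) abort_modra("unknown sample")
  if (is.na(d_idx) || d_idx < 1 || d_idx > fit$model_config$n_drugs) abort_modra("unknown drug")
  tensors <- dataset_tensors(data, fit$train_config$views_enabled)
  # attribution works in the network's input space: the sample's view
  # vectors after the fit's stored gene standardisation + L2 normalisation
  x <- apply_normalizer(lapply(tensors$x, function(m) m[, s_idx, drop = FALSE]),
                        fit$normalizer)
  views <- names(data$views)
  if (method == "grad_x_input") {
    dx <- input_gradient(fit, x, d_idx)
    scores <- lapply(seq_along(x), function(i) abs(dx[[i]] * x[[i]])[, 1L])
  } else {
    base <- model_forward(x, fit$params, fit$model_config,
                          use_attention = fit$train_config$use_attention,
                          compute_alignment = FALSE)$pred[d_idx, 1L]
    scores <- lapply(seq_along(x), function(i) {
      g <- nrow(x[[i]])
      out <- numeric(g)
      for (gi in seq_len(g)) {
        if (x[[i]][gi, 1L] == 0) next  # zeroing a zero changes nothing
        xo <- x
        xo[[i]][gi, 1L] <- 0
        out[gi] <- abs(model_forward(
          xo, fit$params, fit$model_config,
          use_attention = fit$train_config$use_attention,
          compute_alignment = FALSE
        )$pred[d_idx, 1L] - base)
      }
      out
    })
  }
  out <- dplyr::bind_rows(lapply(seq_along(scores), function(i) {
    tibble::tibble(gene_id = rownames(tensors$x[[i]]), view = views[i],
                   score = unname(scores[[i]]))
  })) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id)
  attr(out, "method") <- method
  attr(out, "sample_id") <- sample_ids(data)[s_idx]
  attr(out, "drug_id") <- fit$drug_ids[d_idx]
  class(out) <- c("modra_attribution", class(out))
  out
}

#' Select the top fraction of genes by attribution score
#'
#' Takes the top `ceiling(q * N)` genes over all views (N = total genes),
#' descending by score with gene id as the deterministic tiebreak. The
#' default 3% mirrors the case-study convention.
#'
#' @param attr A `modra_attribution` tibble (or any tibble with `gene_id`
#'   and `score`).
#' @param q Fraction in (0, 1\] (default 0.03).
#' @return The selected rows, in rank order.
#' @export
select_top_genes <- function(attr, q = 0.03) {
  if (nrow(attr) == 0L) abort_modra("empty attribution")
  if (q <= 0 || q > 1) abort_modra("`q` must lie in (0, 1]")
  n_top <- ceiling(q * nrow(attr))
  attr |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id) |>
    utils::head(n_top)
}

#' Hypergeometric gene-set enrichment
#'
#' For each gene set, the p-value is the exact upper-tail hypergeometric
#' probability of drawing at least the observed overlap when `|selected|`
#' genes are drawn without replacement from the background, of which
#' `|set within background|` are marked. `-log10(p)` is reported alongside,
#' plus Benjamini-Hochberg adjusted p-values across the tested sets.
#'
#' @param selected Character vector of selected genes; must be a subset of
#'   `background`.
#' @param background Character vector: the attribution universe.
#' @param pathways Named list of character vectors (e.g. from
#'   [read_gmt()]); each set is intersected with the background before
#'   testing.
#' @return A tibble with `pathway`, `overlap`, `pathway_size` (within
#'   background), `selected_size`, `background_size`, `p_value`,
#'   `neg_log10_p`, `p_adjust`, ascending by p-value.
#' @export
hypergeometric_enrichment <- function(selected, background, pathways) {
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background)) {
    abort_modra("selected genes must be a subset of the background")
  }
  if (length(pathways) == 0L) abort_modra("no pathways supplied")
  if (is.null(names(pathways))) abort_modra("`pathways` must be a named list")
  N <- length(background)
  n_sel <- length(selected)
  rows <- lapply(names(pathways), function(nm) {
    set <- intersect(unique(pathways[[nm]]), background)
    K <- length(set)
    k <- length(intersect(set, selected))
    p <- stats::phyper(k - 1, K, N - K, n_sel, lower.tail = FALSE)
    tibble::tibble(pathway = nm, overlap = k, pathway_size = K,
                   selected_size = n_sel, background_size = N, p_value = p)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(neg_log10_p = -log10(.data$p_value),
                  p_adjust = stats::p.adjust(.data$p_value, method = "BH")) |>
    dplyr::arrange(.data$p_value, .data$pathway)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_modra("empty GMT file: %s", path)
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) abort_modra("malformed GMT line: %s", substr(ln, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1), USE.NAMES = FALSE)
  sets
}
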