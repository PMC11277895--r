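#' Training configuration
#'
#' Defaults follow the published protocol: 200 epochs, learning rate 1e-5
#' for the feature extractors and 1e-6 for the attention/predictor
#' parameters, threefold cross-validation. The optimizer family, batch size
#' and initialisation are not stated upstream; Adam with batch size 32 is
#' the default here and every run records its full configuration. Note that
#' both the contrastive alignment loss and literal batch-softmax attention
#' depend on batch composition, so `batch_size` is part of the model
#' definition, not a nuisance parameter.
#'
#' @param epochs Training epochs (default 200; 0 returns the initial
#'   parameters untouched).
#' @param batch_size Minibatch size (default 32).
#' @param lr_extractor Learning rate for extractor parameters (default
#'   1e-5).
#' @param lr_predictor Learning rate for attention and predictor parameters
#'   (default 1e-6).
#' @param folds Cross-validation folds (default 3).
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @param use_alignment Include the alignment loss (default `TRUE`); when
#'   `FALSE` the alignment weight is forced to zero (ablation).
#' @param use_attention Use co-attention fusion (default `TRUE`); when
#'   `FALSE` the embeddings are concatenated unweighted (ablation).
#' @param views_enabled Subset of 1:4; views outside it are zeroed
#'   throughout training and prediction (omics-combination experiments).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param normalize_inputs Standardise every gene (training-fold mean/sd)
#'   and then scale every sample's view vector to unit L2 norm before it
#'   enters the network (default `TRUE`). The statistics are computed on
#'   the training samples only, stored in the fit and re-applied at
#'   prediction time. Comparable per-sample input norms keep the soft
#'   alignment target from being dominated by large-norm samples.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 32L, lr_extractor = 1e-5,
                         lr_predictor = 1e-6, folds = 3L, seed = 0L,
                         use_alignment = TRUE, use_attention = TRUE,
                         views_enabled = 1:4, optimizer = c("adam", "sgd"),
                         normalize_inputs = TRUE) {
  optimizer <- match.arg(optimizer)
  if (epochs < 0) abort_modra("`epochs` must be >= 0")
  if (batch_size < 1) abort_modra("`batch_size` must be >= 1")
  if (folds < 2) abort_modra("`folds` must be >= 2")
  if (!all(views_enabled %in% 1:4) || length(views_enabled) < 1) {
    abort_modra("`views_enabled` must be a nonempty subset of 1:4")
  }
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr_extractor = lr_extractor, lr_predictor = lr_predictor,
    folds = as.integer(folds), seed = as.integer(seed),
    use_alignment = isTRUE(use_alignment), use_attention = isTRUE(use_attention),
    views_enabled = sort(unique(as.integer(views_enabled))),
    optimizer = optimizer, normalize_inputs = isTRUE(normalize_inputs)
  ), class = "train_config")
}

# ---- loss + gradients for one batch -------------------------------------

# x_list: genes x bs per view; y, miss: drugs x bs
loss_and_grads <- function(x_list, y, miss, params, cfg, tcfg, training = TRUE) {
  use_align <- tcfg$use_alignment && cfg$gamma_align > 0
  fw <- model_forward(x_list, params, cfg, training = training,
                      use_attention = tcfg$use_attention,
                      compute_alignment = use_align)
  loss_reg <- regression_loss(fw$pred, y, miss, loss = cfg$loss)
  loss_la <- if (use_align) fw$alignment$loss else 0
  gamma_align_eff <- if (tcfg$use_alignment) cfg$gamma_align else 0
  loss_tot <- total_loss(loss_reg, loss_la, cfg$gamma_reg, gamma_align_eff)

  dpred <- cfg$gamma_reg * regression_loss_backward(fw$pred, y, miss, cfg$loss)
  pb <- predictor_backward(dpred, fw$cache$predictor, params$predictor)
  d2 <- cfg$d2
  if (tcfg$use_attention) {
    ab <- coattention_backward(pb$dZp, fw$cache$attention, params$attention, cfg)
    grad_att <- ab$grad
    dz <- ab$dz
  } else {
    grad_att <- zero_like(params$attention)
    dz <- lapply(seq_along(x_list), function(i) {
      pb$dZp[((i - 1L) * d2 + 1L):(i * d2), , drop = FALSE]
    })
  }
  if (use_align) {
    dz_align <- alignment_backward(fw$z, fw$alignment, cfg$tau,
                                   detach_target = cfg$detach_target)
    dz <- lapply(seq_along(dz), function(i) {
      dz[[i]] + gamma_align_eff * dz_align[[i]]
    })
  }
  grad_ext <- lapply(seq_along(x_list), function(i) {
    extractor_backward(dz[[i]], fw$cache$extract[[i]], params$extractor[[i]])$grad
  })
  list(
    loss_reg = loss_reg, loss_la = loss_la, loss_total = loss_tot,
    pred = fw$pred,
    grads = structure(list(extractor = grad_ext, attention = grad_att,
                           predictor = pb$grad), class = "modra_params")
  )
}

# nested list of arrays -> same structure filled with zeros
zero_like <- function(p) {
  walk <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) return(lapply(x, walk))
    x * 0
  }
  walk(p)
}

# elementwise binary op over two parameter trees
tree_map2 <- function(a, b, f) {
  walk <- function(x, y) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) return(Map(walk, x, y))
    f(x, y)
  }
  walk(a, b)
}

# ---- optimizers ----------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr_for_group,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (group in names(params)) {
    lr <- lr_for_group[[group]]
    walk <- function(p, g, m, v) {
      if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
      if (is.list(p)) {
        out <- Map(walk, p, g, m, v)
        return(list(p = lapply(out, `[[`, "p"),
                    m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v")))
      }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      p_new <- p - lr * mhat / (sqrt(vhat) + eps)
      attributes(p_new) <- attributes(p)
      list(p = p_new, m = m, v = v)
    }
    out <- walk(params[[group]], grads[[group]],
                state$m[[group]], state$v[[group]])
    params[[group]] <- out$p
    state$m[[group]] <- out$m
    state$v[[group]] <- out$v
  }
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr_for_group) {
  for (group in names(params)) {
    lr <- lr_for_group[[group]]
    params[[group]] <- tree_map2(params[[group]], grads[[group]],
                                 function(p, g) {
                                   p_new <- p - lr * g
                                   attributes(p_new) <- attributes(p)
                                   p_new
                                 })
  }
  params
}

# ---- data plumbing -------------------------------------------------------

# per-view gene standardisation statistics, computed on training columns
make_normalizer <- function(x_list, train_cols) {
  lapply(x_list, function(m) {
    sub <- m[, train_cols, drop = FALSE]
    center <- unname(rowMeans(sub))
    scale <- unname(apply(sub, 1L, stats::sd))
    scale[!is.finite(scale) | scale == 0] <- 1
    list(center = center, scale = scale)
  })
}

# standardise genes, then L2-normalise each sample (column) within a view
apply_normalizer <- function(x_list, normalizer) {
  if (is.null(normalizer)) return(x_list)
  lapply(seq_along(x_list), function(i) {
    m <- (x_list[[i]] - normalizer[[i]]$center) / normalizer[[i]]$scale
    nrm <- sqrt(colSums(m^2))
    nrm[nrm == 0] <- 1
    m / rep(nrm, each = nrow(m))
  })
}

# dataset -> list(x = list of genes x n matrices, y = drugs x n, miss)
dataset_tensors <- function(data, views_enabled = 1:4) {
  x <- lapply(seq_along(data$views), function(i) {
    v <- data$views[[i]]
    if (any(v$missing_mask)) {
      abort_modra("view %s still contains missing values; preprocess first",
                  v$view_kind)
    }
    m <- t(v$values)
    if (!(i %in% views_enabled)) m[] <- 0
    m
  })
  list(x = x, y = t(data$response$values), miss = t(data$response$missing_mask))
}

#' Train the multi-omics drug-response model
#'
#' Minibatch gradient descent on the composite loss (regression +
#' alignment), with the extractor parameters updated at `lr_extractor` and
#' the attention/predictor parameters at `lr_predictor`. Fully reproducible
#' from `tcfg$seed`. Optional held-out indices are evaluated (dropout off)
#' at the end of every epoch.
#'
#' @param data A complete [multiomics_dataset()].
#' @param mcfg A [model_config()]; `n_drugs` must match the data.
#' @param tcfg A [train_config()].
#' @param val_idx Optional integer sample indices used only for per-epoch
#'   validation-loss reporting (never for updates).
#' @return A `modra_fit`: parameters, per-epoch history tibble, configs and
#'   data layout.
#' @export
train_model <- function(data, mcfg, tcfg, val_idx = NULL) {
  stopifnot(inherits(data, "multiomics_dataset"),
            inherits(mcfg, "model_config"), inherits(tcfg, "train_config"))
  n <- n_samples(data)
  if (n == 0L) abort_modra("empty dataset")
  if (mcfg$n_drugs != length(drug_ids(data))) {
    abort_modra("model predicts %d drugs but data has %d",
                mcfg$n_drugs, length(drug_ids(data)))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  tensors <- dataset_tensors(data, tcfg$views_enabled)
  normalizer <- NULL
  if (tcfg$normalize_inputs) {
    normalizer <- make_normalizer(tensors$x, train_idx)
    tensors$x <- apply_normalizer(tensors$x, normalizer)
  }
  gene_counts <- vapply(tensors$x, nrow, integer(1))
  params <- init_model_params(gene_counts, mcfg, seed = tcfg$seed)
  history <- list()
  fit <- function(params, history) {
    structure(list(
      params = params,
      history = if (length(history)) dplyr::bind_rows(history) else empty_history(),
      model_config = mcfg, train_config = tcfg,
      gene_counts = gene_counts, drug_ids = drug_ids(data),
      view_kinds = names(data$views), normalizer = normalizer
    ), class = "modra_fit")
  }
  if (tcfg$epochs == 0L) return(fit(params, history))

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(tcfg$seed + 1L)
  lr_for_group <- list(extractor = tcfg$lr_extractor,
                       attention = tcfg$lr_predictor,
                       predictor = tcfg$lr_predictor)
  opt_state <- if (tcfg$optimizer == "adam") adam_init(params) else NULL
  slice <- function(idx) {
    list(x = lapply(tensors$x, function(m) m[, idx, drop = FALSE]),
         y = tensors$y[, idx, drop = FALSE],
         miss = tensors$miss[, idx, drop = FALSE])
  }
  for (epoch in seq_len(tcfg$epochs)) {
    order <- sample(train_idx)
    starts <- seq(1L, length(order), by = tcfg$batch_size)
    reg_sum <- la_sum <- tot_sum <- 0
    nb <- 0L
    for (s in starts) {
      idx <- order[s:min(s + tcfg$batch_size - 1L, length(order))]
      b <- slice(idx)
      step <- loss_and_grads(b$x, b$y, b$miss, params, mcfg, tcfg, training = TRUE)
      if (tcfg$optimizer == "adam") {
        upd <- adam_step(params, step$grads, opt_state, lr_for_group)
        params <- upd$params
        opt_state <- upd$state
      } else {
        params <- sgd_step(params, step$grads, lr_for_group)
      }
      reg_sum <- reg_sum + step$loss_reg
      la_sum <- la_sum + step$loss_la
      tot_sum <- tot_sum + step$loss_total
      nb <- nb + 1L
    }
    rec <- tibble::tibble(
      epoch = epoch,
      train_reg = reg_sum / nb, train_la = la_sum / nb, train_total = tot_sum / nb,
      val_reg = NA_real_, val_la = NA_real_, val_total = NA_real_
    )
    if (length(val_idx)) {
      vb <- slice(val_idx)
      ev <- loss_and_grads(vb$x, vb$y, vb$miss, params, mcfg, tcfg, training = FALSE)
      rec$val_reg <- ev$loss_reg
      rec$val_la <- ev$loss_la
      rec$val_total <- ev$loss_total
    }
    history[[epoch]] <- rec
  }
  fit(params, history)
}

empty_history <- function() {
  tibble::tibble(epoch = integer(), train_reg = double(), train_la = double(),
                 train_total = double(), val_reg = double(), val_la = double(),
                 val_total = double())
}

#' @export
print.modra_fit <- function(x, ...) {
  cat(sprintf(
    "<modra_fit> %d drugs, %d epochs trained (alignment: %s, attention: %s)\n",
    x$model_config$n_drugs, nrow(x$history),
    x$train_config$use_alignment, x$train_config$use_attention
  ))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train loss: reg %.4f, align %.4f\n",
                last$train_reg, last$train_la))
  }
  invisible(x)
}

#' Predict drug responses for dataset samples
#'
#' Runs the forward pass with dropout off, re-applying the training-fold
#' input normalisation stored in the fit. `masked_view` zeroes the view's
#' *raw* input slice before normalisation, so the result is identical to
#' physically zeroing that view's input file and re-running. In literal
#' batch-softmax mode predictions depend on which samples share the batch;
#' for reproducibility the whole requested slice is run as one batch.
#'
#' @param object A `modra_fit`.
#' @param data A complete [multiomics_dataset()] with the same view layout
#'   the model was trained on.
#' @param sample_idx Integer indices of the samples to predict (default
#'   all).
#' @param masked_view Optional view index in 1:4 to zero before extraction.
#' @param ... Unused.
#' @return A samples x drugs matrix of predicted log(IC50).
#' @export
predict.modra_fit <- function(object, data, sample_idx = NULL,
                              masked_view = NULL, ...) {
  tensors <- dataset_tensors(data, object$train_config$views_enabled)
  if (is.null(sample_idx)) sample_idx <- seq_len(n_samples(data))
  x <- lapply(tensors$x, function(m) m[, sample_idx, drop = FALSE])
  if (!is.null(masked_view)) {
    if (!(masked_view %in% seq_along(x))) abort_modra("invalid view index")
    x[[masked_view]][] <- 0
  }
  x <- apply_normalizer(x, object$normalizer)
  fw <- model_forward(x, object$params, object$model_config, training = FALSE,
                      use_attention = object$train_config$use_attention,
                      compute_alignment = FALSE)
  out <- t(fw$pred)
  dimnames(out) <- list(sample_ids(data)[sample_idx], object$drug_ids)
  out
}

#' Seeded disjoint fold assignment
#'
#' @param n Number of samples.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in 1:folds.
#' @export
make_folds <- function(n, folds, seed = 0L) {
  if (folds > n) abort_modra("more folds than samples")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

#' k-fold cross-validation of the full pipeline
#'
#' Partitions samples into `tcfg$folds` disjoint folds with a seeded
#' shuffle; for each fold trains on the remainder (fresh parameters, fold-
#' specific seed) and evaluates on the held-out fold. Binarization
#' thresholds for F1/AUROC are per-drug medians computed on the training
#' fold only, so held-out samples never leak into thresholds or updates.
#'
#' @param data A complete [multiomics_dataset()].
#' @param mcfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param pooled Aggregate F1/AUROC over all drug-sample pairs instead of
#'   macro-averaging over drugs (default `FALSE`).
#' @return A `modra_cv`: `folds` (per-fold metric tibble), `summary`
#'   (mean and sample sd per metric), `fold_assignment`, and the per-fold
#'   fits' histories.
#' @export
run_cv <- function(data, mcfg, tcfg, pooled = FALSE) {
  n <- n_samples(data)
  fold_of <- make_folds(n, tcfg$folds, seed = tcfg$seed)
  rows <- list()
  histories <- list()
  for (f in seq_len(tcfg$folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    tcfg_f <- tcfg
    tcfg_f$seed <- tcfg$seed + f
    fit <- train_model(subset_dataset(data, train_idx), mcfg, tcfg_f)
    histories[[f]] <- fit$history
    pred_test <- predict(fit, data, sample_idx = test_idx)
    rep <- metrics_report(
      pred = pred_test,
      y = data$response$values[test_idx, , drop = FALSE],
      mask = data$response$missing_mask[test_idx, , drop = FALSE],
      train_y = data$response$values[train_idx, , drop = FALSE],
      train_mask = data$response$missing_mask[train_idx, , drop = FALSE],
      pooled = pooled
    )
    rows[[f]] <- tibble::tibble(fold = f, mse = rep$mse, f1 = rep$f1,
                                auroc = rep$auroc)
  }
  folds_tbl <- dplyr::bind_rows(rows)
  summary_tbl <- tidyr::pivot_longer(folds_tbl, -"fold",
                                     names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
  structure(list(folds = folds_tbl, summary = summary_tbl,
                 fold_assignment = fold_of, histories = histories),
            class = "modra_cv")
}

#' @export
print.modra_cv <- function(x, ...) {
  cat(sprintf("<modra_cv> %d folds\n", nrow(x$folds)))
  print(x$summary)
  invisible(x)
}
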