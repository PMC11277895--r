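test_that("zero epochs returns initial parameters and empty history", {
  d <- tiny_dataset(seed = 2, n = 10)
  mcfg <- tiny_mcfg()
  tcfg <- train_config(epochs = 0, seed = 4)
  fit <- train_model(d, mcfg, tcfg)
  expect_equal(nrow(fit$history), 0L)
  expect_identical(fit$params,
                   init_model_params(fit$gene_counts, mcfg, seed = tcfg$seed))
})

test_that("training reduces the regression loss on synthetic data", {
  d <- generate_dataset(simulation_config(
    n_samples = 200, genes_per_view = rep(20L, 4), latent_rank = 3,
    response_noise_sd = 0.1, n_drugs = 5, seed = 0
  ))
  mcfg <- tiny_mcfg(n_drugs = 5)
  tcfg <- train_config(epochs = 50, batch_size = 32, lr_extractor = 1e-3,
                       lr_predictor = 1e-3, seed = 0)
  fit <- train_model(d, mcfg, tcfg)
  expect_lt(fit$history$train_reg[50], fit$history$train_reg[1])
})

test_that("training is reproducible from its seed", {
  d <- tiny_dataset(seed = 5, n = 24)
  tcfg <- train_config(epochs = 3, batch_size = 8, lr_extractor = 1e-3,
                       lr_predictor = 1e-3, seed = 9)
  f1 <- train_model(d, tiny_mcfg(), tcfg)
  f2 <- train_model(d, tiny_mcfg(), tcfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("ablation switches do what they claim", {
  d <- tiny_dataset(seed = 7, n = 16)
  mcfg <- tiny_mcfg()
  # alignment off: recorded alignment loss contributes zero
  fit_no_la <- train_model(d, mcfg, train_config(
    epochs = 2, batch_size = 8, lr_extractor = 1e-3, lr_predictor = 1e-3,
    seed = 2, use_alignment = FALSE))
  expect_true(all(fit_no_la$history$train_la == 0))
  expect_equal(fit_no_la$history$train_total, fit_no_la$history$train_reg)
  # attention off: forward equals the concatenation pathway on a probe batch
  tensors <- modra:::dataset_tensors(d)
  x <- lapply(tensors$x, function(m) m[, 1:4])
  params <- init_model_params(vapply(x, nrow, integer(1)), mcfg, seed = 0)
  fw <- model_forward(x, params, mcfg, use_attention = FALSE)
  z <- lapply(seq_along(x), function(i) feature_extract(x[[i]], params$extractor[[i]]))
  expect_equal(fw$pred, predict_head(do.call(rbind, z), params$predictor))
  # disabled views are zeroed throughout
  fit_v <- train_model(d, mcfg, train_config(
    epochs = 1, batch_size = 8, lr_extractor = 1e-3, lr_predictor = 1e-3,
    seed = 2, views_enabled = c(1, 3)))
  t2 <- modra:::dataset_tensors(d, c(1, 3))
  expect_true(all(t2$x[[2]] == 0) && all(t2$x[[4]] == 0))
})

test_that("fold assignment partitions samples evenly and reproducibly", {
  f <- make_folds(9, 3, seed = 1)
  expect_equal(sort(unique(f)), 1:3)
  expect_equal(unname(table(f)), rep(3L, 3), ignore_attr = TRUE)
  expect_identical(f, make_folds(9, 3, seed = 1))
  expect_false(identical(f, make_folds(9, 3, seed = 2)))
  expect_error(make_folds(2, 3), "more folds")
})

test_that("cross-validation computes thresholds from training folds only", {
  d <- tiny_dataset(seed = 8, n = 30)
  mcfg <- tiny_mcfg()
  tcfg <- train_config(epochs = 2, batch_size = 8, lr_extractor = 1e-3,
                       lr_predictor = 1e-3, folds = 3, seed = 3)
  cv <- run_cv(d, mcfg, tcfg)
  expect_equal(nrow(cv$folds), 3L)
  expect_setequal(unique(cv$fold_assignment), 1:3)
  expect_equal(nrow(cv$summary), 3L)
  # recompute fold-1 thresholds independently from the training fold
  test_idx <- which(cv$fold_assignment == 1)
  train_idx <- which(cv$fold_assignment != 1)
  manual_thr <- apply(d$response$values[train_idx, , drop = FALSE], 2, median)
  tcfg_f <- tcfg
  tcfg_f$seed <- tcfg$seed + 1
  fit <- train_model(modra:::subset_dataset(d, train_idx), mcfg, tcfg_f)
  rep <- metrics_report(
    pred = predict(fit, d, sample_idx = test_idx),
    y = d$response$values[test_idx, , drop = FALSE],
    mask = d$response$missing_mask[test_idx, , drop = FALSE],
    train_y = d$response$values[train_idx, , drop = FALSE],
    train_mask = d$response$missing_mask[train_idx, , drop = FALSE]
  )
  expect_equal(rep$per_drug$threshold, unname(manual_thr))
  expect_equal(cv$folds$mse[1], rep$mse)
  # summary aggregates per-fold metrics with mean and sample sd
  expect_equal(cv$summary$mean[cv$summary$metric == "mse"], mean(cv$folds$mse))
  expect_equal(cv$summary$sd[cv$summary$metric == "mse"], sd(cv$folds$mse))
})

test_that("input normalisation uses training statistics and is stored", {
  d <- tiny_dataset(seed = 9, n = 20)
  tcfg <- train_config(epochs = 1, batch_size = 8, lr_extractor = 1e-3,
                       lr_predictor = 1e-3, seed = 0)
  fit <- train_model(d, tiny_mcfg(), tcfg, val_idx = 16:20)
  tensors <- modra:::dataset_tensors(d)
  expect_equal(fit$normalizer[[1]]$center,
               unname(rowMeans(tensors$x[[1]][, 1:15])))
  # normalized columns have unit L2 norm
  xn <- modra:::apply_normalizer(tensors$x, fit$normalizer)
  expect_equal(unname(colSums(xn[[2]]^2)), rep(1, 20), tolerance = 1e-12)
  # normalize_inputs = FALSE leaves tensors untouched and stores NULL
  fit_raw <- train_model(d, tiny_mcfg(), train_config(
    epochs = 0, seed = 0, normalize_inputs = FALSE))
  expect_null(fit_raw$normalizer)
})
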