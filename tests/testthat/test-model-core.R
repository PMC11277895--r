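test_that("feature extractor matches its hand cases and the loop oracle", {
  inst <- random_instance(1, g = c(4, 4, 4, 4), bs = 3, d2 = 4)
  p <- inst$params$extractor[[1]]
  x <- inst$x[[1]]
  # all-zero parameters -> zero output
  p0 <- lapply(p, function(w) w * 0)
  expect_equal(feature_extract(x, p0), matrix(0, 4, 3))
  # first layer forced negative -> z = ReLU(b2)
  pneg <- p
  pneg$W1 <- p$W1 * 0
  pneg$b1 <- rep(-5, length(p$b1))
  zneg <- feature_extract(x, pneg)
  expect_equal(zneg, matrix(pmax(p$b2, 0), 4, 3), ignore_attr = TRUE)
  # loop-oracle equivalence on random instances
  for (seed in 1:10) {
    inst <- random_instance(seed)
    z <- feature_extract(inst$x[[1]], inst$params$extractor[[1]])
    expect_equal(z, oracle_feature_extract(inst$x[[1]], inst$params$extractor[[1]]),
                 tolerance = 1e-6)
    expect_true(all(z >= 0))
  }
  expect_error(feature_extract(matrix(0, 2, 2), p), "expects")
})

test_that("sample similarity is the cross-view inner-product matrix", {
  # orthonormal columns -> identity
  z <- diag(3)
  expect_equal(sample_similarity(z, z), diag(3))
  expect_equal(sample_similarity(z, z * 0), matrix(0, 3, 3))
  set.seed(2)
  zi <- matrix(rnorm(6), 3, 2)
  zj <- matrix(rnorm(6), 3, 2)
  expect_equal(sample_similarity(zi, zj), oracle_similarity(zi, zj))
  expect_error(sample_similarity(zi, matrix(0, 2, 2)), "shapes")
})

test_that("alignment target is row-stochastic with the documented cases", {
  # constant similarity matrices -> uniform rows
  S <- replicate(4, matrix(3, 5, 5), simplify = FALSE)
  Tm <- alignment_target(S, tau = 1)
  expect_equal(Tm, matrix(0.2, 5, 5))
  # bs = 2 direct evaluation: all S_ii = diag(2, 2), tau = 1
  S2 <- replicate(4, diag(c(2, 2)), simplify = FALSE)
  T2 <- alignment_target(S2, tau = 1)
  expect_equal(T2[1, ], c(exp(2), 1) / (exp(2) + 1))
  # large tau flattens toward uniform
  T_hot <- alignment_target(S2, tau = 1000)
  expect_lt(max(abs(T_hot - 0.5)), 1e-3)
  expect_error(alignment_target(S2, tau = 0), "positive")
  for (seed in 1:5) {
    set.seed(seed)
    Sr <- replicate(4, matrix(rnorm(16), 4, 4), simplify = FALSE)
    expect_equal(rowSums(alignment_target(Sr, runif(1, 0.2, 3))), rep(1, 4),
                 tolerance = 1e-6)
  }
})

test_that("alignment loss attains the Gibbs bound iff embeddings coincide", {
  set.seed(9)
  # identical embeddings: loss = 6 * mean row entropy of T
  z0 <- matrix(abs(rnorm(12)), 4, 3)
  st <- alignment_loss(list(z0, z0, z0, z0), tau = 0.7)
  H <- -mean(rowSums(st$target * log(st$target)))
  expect_equal(st$loss, 6 * H, tolerance = 1e-6)
  # single sample: T = [1], loss = 0
  z1 <- matrix(abs(rnorm(4)), 4, 1)
  expect_equal(alignment_loss(list(z1, z1 * 2, z1 + 1, z1), tau = 1)$loss, 0)
  expect_error(alignment_loss(list(z1), tau = 1), "two views")
  # Gibbs inequality on 100 random embedding sets
  for (seed in 1:100) {
    set.seed(seed)
    bs <- sample(2:5, 1)
    d2 <- sample(2:6, 1)
    tau <- runif(1, 0.3, 2)
    z <- lapply(1:4, function(i) matrix(rnorm(d2 * bs), d2, bs))
    st <- alignment_loss(z, tau)
    H <- -mean(rowSums(st$target * log(pmax(st$target, 1e-300))))
    expect_gte(st$loss, 6 * H - 1e-6)
  }
})

test_that("affinity matrix matches tanh bilinear oracle and stays in (-1,1)", {
  # zero embeddings -> zero affinity
  z <- matrix(0, 2, 3)
  M <- diag(2)
  expect_equal(affinity_matrix(z, z, M), matrix(0, 3, 3))
  # unit-basis scalar case: tanh(1)
  e1 <- matrix(c(1, 0), 2, 1)
  expect_equal(affinity_matrix(e1, e1, diag(2)), matrix(tanh(1), 1, 1))
  for (seed in 1:10) {
    set.seed(seed)
    d2 <- sample(2:5, 1)
    bs <- sample(1:4, 1)
    zi <- matrix(rnorm(d2 * bs), d2, bs)
    zj <- matrix(rnorm(d2 * bs), d2, bs)
    M <- matrix(rnorm(d2 * d2), d2, d2)
    Fm <- affinity_matrix(zi, zj, M)
    expect_equal(Fm, oracle_affinity(zi, zj, M), tolerance = 1e-6)
    expect_true(all(abs(Fm) < 1))
  }
  expect_error(affinity_matrix(matrix(0, 2, 2), matrix(0, 3, 2), diag(2)), "shapes")
})

test_that("co-attention fusion matches the loop oracle in both softmax modes", {
  for (seed in 1:12) {
    inst <- random_instance(seed, bs = 3, d2 = 5, k = 4)
    for (literal in c(TRUE, FALSE)) {
      cfg <- inst$cfg
      cfg$literal_batch_softmax <- literal
      Zp <- coattention_fuse(inst$z, inst$params$attention, cfg)
      expect_equal(unclass(Zp), oracle_coattention(inst$z, inst$params$attention, literal),
                   tolerance = 1e-5, ignore_attr = TRUE)
      A <- attr(Zp, "weights")
      if (literal) expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-6)
      else expect_equal(colSums(A), rep(1, 3), tolerance = 1e-6)
    }
  }
})

test_that("co-attention degenerate cases behave as the equations dictate", {
  inst <- random_instance(3, bs = 1, d2 = 4, k = 3)
  # single sample, literal mode: every weight is 1 -> plain concatenation
  cfg <- inst$cfg
  cfg$literal_batch_softmax <- TRUE
  z1 <- lapply(inst$z, function(m) m[, 1, drop = FALSE])
  Zp <- coattention_fuse(z1, inst$params$attention, cfg)
  expect_equal(unclass(Zp), do.call(rbind, z1), ignore_attr = TRUE)
  # zero affinities (z_j = 0 for j != i makes all F rows zero): H_i = tanh(Wz_i z_i)
  p <- inst$params$attention
  z <- list(inst$z[[1]], inst$z[[1]] * 0, inst$z[[1]] * 0, inst$z[[1]] * 0)
  fw <- modra:::coattention_forward(z, p, cfg)
  expect_equal(fw$H[[1]], tanh(p$Wz[[1]] %*% z[[1]]))
})

test_that("prediction head matches the loop oracle and its bias cases", {
  inst <- random_instance(4, bs = 3, d2 = 4)
  p <- inst$params$predictor
  Zp <- matrix(rnorm(16 * 3), 16, 3)
  # all parameters zero -> zero prediction
  p0 <- lapply(p, function(w) w * 0)
  expect_equal(predict_head(Zp, p0), matrix(0, 3, 3))
  # bias-only model -> constant per-drug output
  pb <- p0
  pb$b5 <- c(1.5, -2, 0.25)
  expect_equal(predict_head(Zp, pb), matrix(pb$b5, 3, 3))
  for (seed in 1:10) {
    inst <- random_instance(seed, bs = 2)
    Zp <- matrix(rnorm(4 * inst$d2 * 2), 4 * inst$d2, 2)
    expect_equal(predict_head(Zp, inst$params$predictor),
                 oracle_predict_head(Zp, inst$params$predictor), tolerance = 1e-6)
  }
  expect_error(predict_head(matrix(0, 3, 2), p), "expects")
})

test_that("masked regression loss follows the stated contracts", {
  y <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(regression_loss(y, y), 0)
  pred <- y + matrix(c(1, -1, 0, 0), 2, 2)
  expect_equal(regression_loss(pred[, 1, drop = FALSE], y[, 1, drop = FALSE]), 1)
  # masked entry excluded from sum and count
  pred2 <- y + matrix(c(2, 999, 0, 0), 2, 2)
  mask <- matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2)
  expect_equal(regression_loss(pred2, y, mask), 4)
  expect_equal(regression_loss(pred2, y, mask, loss = "mae"), 2)
  expect_error(regression_loss(y, y, matrix(TRUE, 2, 2)), "no observed")
})

test_that("total loss is the weighted sum with ablation behaviour", {
  expect_equal(total_loss(0.5, 1.5), 2)
  expect_equal(total_loss(0.5, 1.5, gamma_align = 0), 0.5)
  expect_equal(total_loss(3, 7, 0, 0), 0)
})

test_that("forward pass: masking, determinism, shapes", {
  inst <- random_instance(11, bs = 4, d2 = 5)
  cfg <- inst$cfg
  fw <- model_forward(inst$x, inst$params, cfg)
  expect_equal(dim(fw$pred), c(3, 4))
  # masked_view equals physically zeroed input
  x0 <- inst$x
  x0[[2]] <- x0[[2]] * 0
  expect_equal(model_forward(inst$x, inst$params, cfg, masked_view = 2)$pred,
               model_forward(x0, inst$params, cfg)$pred)
  expect_error(model_forward(inst$x, inst$params, cfg, masked_view = 9), "view index")
  # deterministic with dropout off
  expect_identical(fw$pred, model_forward(inst$x, inst$params, cfg)$pred)
  # bs = 1 still gives D x 1
  x1 <- lapply(inst$x, function(m) m[, 1, drop = FALSE])
  expect_equal(dim(model_forward(x1, inst$params, cfg)$pred), c(3, 1))
})

test_that("batch permutation permutes outputs identically in both modes", {
  inst <- random_instance(13, bs = 4, d2 = 5)
  perm <- c(3, 1, 4, 2)
  xp <- lapply(inst$x, function(m) m[, perm, drop = FALSE])
  for (literal in c(TRUE, FALSE)) {
    cfg <- inst$cfg
    cfg$literal_batch_softmax <- literal
    base <- model_forward(inst$x, inst$params, cfg)$pred
    permed <- model_forward(xp, inst$params, cfg)$pred
    expect_equal(permed, base[, perm], tolerance = 1e-10)
  }
})

test_that("checkpoints round-trip parameters bit-exactly", {
  d <- tiny_dataset(seed = 6, n = 12)
  tcfg <- train_config(epochs = 2, batch_size = 4, lr_extractor = 1e-3,
                       lr_predictor = 1e-3, seed = 1)
  fit <- train_model(d, tiny_mcfg(), tcfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  back <- checkpoint_to_fit(path)
  expect_identical(back$params, fit$params)
  expect_identical(back$normalizer, fit$normalizer)
  expect_equal(unclass(back$model_config), unclass(fit$model_config))
  # predictions identical through the restored fit
  expect_identical(predict(fit, d), predict(back, d))
})
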