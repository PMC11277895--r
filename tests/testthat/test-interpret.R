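fit_tiny <- function(seed = 0, n = 24, epochs = 3, ...) {
  d <- tiny_dataset(seed = seed, n = n)
  tcfg <- train_config(epochs = epochs, batch_size = 8, lr_extractor = 1e-3,
                       lr_predictor = 1e-3, seed = seed, ...)
  list(fit = train_model(d, tiny_mcfg(), tcfg), data = d)
}

test_that("masking importance has the right shape and masking semantics", {
  tf <- fit_tiny()
  imp <- omics_mask_importance(tf$fit, tf$data)
  expect_equal(nrow(imp), 3L * 4L)  # D x 4 views
  expect_equal(imp$delta, imp$masked_mse - imp$baseline_mse)
  # masked predictions equal predictions on physically zeroed input data
  zeroed <- tf$data
  zv <- zeroed$views[[2]]
  zv$values[] <- 0
  zeroed$views[[2]] <- modra:::omics_matrix(zv$values, zv$view_kind, strict = FALSE)
  expect_equal(predict(tf$fit, tf$data, masked_view = 2),
               predict(tf$fit, zeroed))
})

test_that("a view with an all-zero extractor contributes zero delta", {
  tf <- fit_tiny(seed = 1)
  fit <- tf$fit
  fit$params$extractor[[3]] <- lapply(fit$params$extractor[[3]], function(w) w * 0)
  imp <- omics_mask_importance(fit, tf$data)
  expect_equal(imp$delta[imp$view == "methylation"], rep(0, 3))
})

test_that("gene attribution: dead input paths score zero under both methods", {
  tf <- fit_tiny(seed = 2)
  fit <- tf$fit
  # kill gene 4 of view 1 in the first layer
  fit$params$extractor[[1]]$W1[, 4] <- 0
  for (method in c("grad_x_input", "occlusion")) {
    attr_tbl <- gene_attribution(fit, tf$data, sample_id = 1, drug = 1,
                                 method = method)
    dead <- attr_tbl$score[attr_tbl$view == "mutation" &
                             attr_tbl$gene_id == "MUT_G0004"]
    expect_equal(dead, 0)
    expect_equal(nrow(attr_tbl), sum(tf$fit$gene_counts))
  }
  expect_error(gene_attribution(tf$fit, tf$data, 1, 99), "unknown drug")
})

# scale weights down and set biases to 1 so every ReLU stays active at the
# data points used below; the network is then exactly linear around them
shrink_to_linear <- function(params) {
  for (i in 1:4) {
    params$extractor[[i]]$W1 <- params$extractor[[i]]$W1 * 0.1
    params$extractor[[i]]$W2 <- params$extractor[[i]]$W2 * 0.1
    params$extractor[[i]]$b1[] <- 1
    params$extractor[[i]]$b2[] <- 1
  }
  params$predictor$W3 <- params$predictor$W3 * 0.1
  params$predictor$W4 <- params$predictor$W4 * 0.1
  params$predictor$W5 <- params$predictor$W5 * 0.1
  params$predictor$b3[] <- 1
  params$predictor$b4[] <- 1
  params
}

test_that("on an effectively linear model grad-x-input matches the chain rule", {
  # two-gene single-view-active model, no attention, inputs tiny so every
  # ReLU keeps a fixed active pattern around x
  d <- tiny_dataset(seed = 3, n = 12)
  mcfg <- tiny_mcfg()
  tcfg <- train_config(epochs = 0, seed = 7, use_attention = FALSE,
                       normalize_inputs = FALSE)
  fit <- train_model(d, mcfg, tcfg)
  # keep every ReLU in a fixed active pattern: shrink weights so the
  # positive biases dominate each pre-activation
  fit$params <- shrink_to_linear(fit$params)
  W_eff <- with(fit$params, predictor$W5 %*% predictor$W4 %*% predictor$W3)
  attr_tbl <- gene_attribution(fit, d, sample_id = 2, drug = 1,
                               method = "grad_x_input")
  x <- modra:::dataset_tensors(d)$x
  # closed-form: |(W5 W4 W3)[drug, block1] W2 W1 * x| per gene of view 1
  lin1 <- W_eff[1, 1:mcfg$d2, drop = FALSE] %*%
    fit$params$extractor[[1]]$W2 %*% fit$params$extractor[[1]]$W1
  expected <- abs(as.numeric(lin1) * x[[1]][, 2])
  got <- attr_tbl[attr_tbl$view == "mutation", ]
  got <- got$score[match(rownames(x[[1]]), got$gene_id)]
  expect_equal(got, unname(expected), tolerance = 1e-8)
})

test_that("occlusion and grad-x-input agree in rank on a near-linear model", {
  d <- tiny_dataset(seed = 4, n = 10)
  tcfg <- train_config(epochs = 0, seed = 8, use_attention = FALSE,
                       normalize_inputs = FALSE)
  fit <- train_model(d, tiny_mcfg(), tcfg)
  fit$params <- shrink_to_linear(fit$params)
  a1 <- gene_attribution(fit, d, 1, 2, method = "grad_x_input")
  a2 <- gene_attribution(fit, d, 1, 2, method = "occlusion")
  merged <- merge(as.data.frame(a1), as.data.frame(a2),
                  by = c("gene_id", "view"))
  keep <- merged$score.x > 0 | merged$score.y > 0
  rho <- cor(merged$score.x[keep], merged$score.y[keep], method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("top-gene selection uses the ceiling rule and id tiebreaks", {
  attr_tbl <- tibble::tibble(
    gene_id = sprintf("G%03d", 1:100),
    view = "expression",
    score = rep(c(5, 1), c(4, 96))
  )
  expect_equal(nrow(select_top_genes(attr_tbl, 0.03)), 3L)
  expect_equal(select_top_genes(attr_tbl, 0.03)$gene_id, c("G001", "G002", "G003"))
  attr150 <- tibble::tibble(gene_id = sprintf("G%03d", 1:150), view = "x",
                            score = runif(150))
  expect_equal(nrow(select_top_genes(attr150, 0.03)), 5L)  # ceiling(4.5)
  expect_equal(nrow(select_top_genes(attr150, 1)), 150L)
  expect_error(select_top_genes(attr150, 0), "q")
})

test_that("hypergeometric enrichment matches the exact combinatorial tail", {
  background <- sprintf("G%03d", 1:100)
  pathway <- background[1:10]
  selected <- c(background[1:5], background[50:54])  # overlap 5
  res <- hypergeometric_enrichment(selected, background,
                                   list(P = pathway))
  expect_equal(res$overlap, 5L)
  expect_equal(res$p_value, oracle_hyper_tail(5, 10, 100, 10), tolerance = 1e-12)
  # zero overlap -> p = 1
  res0 <- hypergeometric_enrichment(background[90:99], background,
                                    list(P = pathway))
  expect_equal(res0$p_value, 1)
  # pathway identical to the selection: minimal p among same-size pathways
  resx <- hypergeometric_enrichment(selected, background, list(
    exact = selected, other = background[20:29]
  ))
  expect_lt(resx$p_value[resx$pathway == "exact"],
            resx$p_value[resx$pathway == "other"])
  expect_error(hypergeometric_enrichment(c("NOT_THERE"), background,
                                         list(P = pathway)), "subset")
})

test_that("enrichment p-values decrease monotonically in the overlap", {
  background <- sprintf("G%03d", 1:60)
  pathway <- background[1:12]
  ps <- vapply(1:8, function(k) {
    selected <- c(pathway[seq_len(k)], setdiff(background, pathway)[seq_len(10 - k)])
    hypergeometric_enrichment(selected, background, list(P = pathway))$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("GMT fixture reads into named gene sets usable end to end", {
  gmt <- read_gmt(system.file("extdata", "toy_pathways.gmt", package = "modra"))
  expect_length(gmt, 5L)
  expect_named(gmt, c("PATHWAY_A", "PATHWAY_B", "PATHWAY_C", "PATHWAY_D", "PATHWAY_E"))
  expect_true(all(c("EXP_G0001", "MET_G0001") %in% gmt$PATHWAY_A))
  # usable against an attribution-style background
  background <- unique(unlist(gmt))
  res <- hypergeometric_enrichment(gmt$PATHWAY_A, background, gmt)
  expect_equal(res$overlap[res$pathway == "PATHWAY_A"], length(gmt$PATHWAY_A))
  expect_equal(res$p_adjust, p.adjust(res$p_value, method = "BH"))
})
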