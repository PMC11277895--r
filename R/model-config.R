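#' Model architecture configuration
#'
#' Dimensions and hyperparameters of the network. Defaults follow the
#' published architecture where stated: first extractor layer `d1 = 1024`,
#' attention dimension `k = 40`, output dimension `D = 31` drugs, dropout
#' 0.2 on each feature extractor, and a 1:1 ratio between the regression and
#' alignment losses. The extractor output width `d2` and the predictor
#' hidden widths `d3`, `d4` are not stated upstream; defaults 256/512/128.
#'
#' @param d1 First extractor layer width (default 1024).
#' @param d2 Extractor output (latent) width (default 256).
#' @param k Attention dimension (default 40).
#' @param d3,d4 Predictor hidden widths (defaults 512, 128).
#' @param n_drugs Output dimension D (default 31).
#' @param tau Temperature of the similarity softmaxes, > 0 (default 1).
#' @param dropout Dropout rate applied after each extractor ReLU during
#'   training (default 0.2).
#' @param gamma_reg,gamma_align Loss weights for the regression and
#'   alignment terms (defaults 1 and 1, the 1:1 ratio).
#' @param literal_batch_softmax Attention-weight softmax axis. `TRUE`
#'   (default) normalises each view's scores over the batch, the literal
#'   reading of the published equation; `FALSE` normalises the four views'
#'   scores per sample, which makes inference independent of batch
#'   composition and is the mode used by the training experiments.
#' @param detach_target Treat the alignment target `T` as a constant per
#'   batch (stop-gradient, default `TRUE`). Letting gradients flow through
#'   the target lets the objective collapse onto a degenerate solution in
#'   which every target row points at one large-norm sample; `FALSE`
#'   computes the exact composite gradient and is mainly useful for
#'   gradient checking.
#' @param loss Regression loss, `"mse"` (default) or `"mae"`.
#' @return A `model_config` list.
#' @export
model_config <- function(d1 = 1024L, d2 = 256L, k = 40L, d3 = 512L, d4 = 128L,
                         n_drugs = 31L, tau = 1, dropout = 0.2,
                         gamma_reg = 1, gamma_align = 1,
                         literal_batch_softmax = TRUE, detach_target = TRUE,
                         loss = c("mse", "mae")) {
  loss <- match.arg(loss)
  dims <- c(d1 = d1, d2 = d2, k = k, d3 = d3, d4 = d4, n_drugs = n_drugs)
  if (any(dims < 1)) abort_modra("all dimensions must be >= 1")
  if (tau <= 0) abort_modra("`tau` must be positive")
  if (dropout < 0 || dropout >= 1) abort_modra("`dropout` must lie in [0, 1)")
  if (gamma_reg < 0 || gamma_align < 0) abort_modra("loss weights must be nonnegative")
  structure(list(
    d1 = as.integer(d1), d2 = as.integer(d2), k = as.integer(k),
    d3 = as.integer(d3), d4 = as.integer(d4), n_drugs = as.integer(n_drugs),
    tau = tau, dropout = dropout, gamma_reg = gamma_reg,
    gamma_align = gamma_align, literal_batch_softmax = literal_batch_softmax,
    detach_target = isTRUE(detach_target), loss = loss
  ), class = "model_config")
}

#' Initialise all learnable tensors
#'
#' He initialisation for the ReLU layers (extractors and predictor), Xavier
#' for the tanh-facing attention tensors, zero biases. Parameters are
#' grouped as `extractor` (per-view `W1`, `b1`, `W2`, `b2`), `attention`
#' (bilinear `M[[i]][[j]]` for the 12 ordered view pairs, per-view `Wz`,
#' `WH`) and `predictor` (`W3`..`W5`, `b3`..`b5`); the training loop keys
#' its two learning rates off these group names.
#'
#' @param gene_counts Integer vector of length 4: input genes per view.
#' @param cfg A [model_config()].
#' @param seed Integer seed for the draws.
#' @return A nested list of numeric arrays, class `modra_params`.
#' @export
init_model_params <- function(gene_counts, cfg, seed = 0L) {
  stopifnot(inherits(cfg, "model_config"), length(gene_counts) == 4L)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
  xavier <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(1 / nc)), nr, nc)
  extractor <- lapply(as.integer(gene_counts), function(g) {
    list(W1 = he(cfg$d1, g), b1 = numeric(cfg$d1),
         W2 = he(cfg$d2, cfg$d1), b2 = numeric(cfg$d2))
  })
  M <- lapply(1:4, function(i) {
    lapply(1:4, function(j) if (i == j) NULL else xavier(cfg$d2, cfg$d2))
  })
  attention <- list(
    M = M,
    Wz = lapply(1:4, function(i) xavier(cfg$k, cfg$d2)),
    WH = lapply(1:4, function(i) xavier(1L, cfg$k))
  )
  predictor <- list(
    W3 = he(cfg$d3, 4L * cfg$d2), b3 = numeric(cfg$d3),
    W4 = he(cfg$d4, cfg$d3), b4 = numeric(cfg$d4),
    W5 = he(cfg$n_drugs, cfg$d4), b5 = numeric(cfg$n_drugs)
  )
  structure(list(extractor = extractor, attention = attention,
                 predictor = predictor),
            class = "modra_params")
}

# ---- checkpoint serialisation -------------------------------------------
# JSON with every numeric payload formatted "%.17g" so doubles round-trip
# bit-exactly (plain JSON number printing caps at ~15 significant digits).

encode_array <- function(x) {
  list(dim = if (is.matrix(x)) dim(x) else length(x),
       data = sprintf("%.17g", as.numeric(x)))
}

decode_array <- function(e) {
  v <- as.numeric(unlist(e$data))
  d <- as.integer(unlist(e$dim))
  if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v
}

encode_params <- function(p) {
  rapply(unclass(p), encode_array, classes = c("matrix", "numeric", "array"),
         how = "replace")
}

decode_params <- function(p) {
  walk <- function(x) {
    if (is.list(x) && !is.null(x$data) && !is.null(x$dim)) return(decode_array(x))
    if (is.list(x)) return(lapply(x, walk))
    x
  }
  structure(walk(p), class = "modra_params")
}

#' Save a fitted model (or bare parameters) to a JSON checkpoint
#'
#' One self-contained JSON file holding the model configuration, the input
#' gene counts, drug identifiers and every parameter tensor. Numeric values
#' are stored with 17 significant digits so [load_checkpoint()] restores
#' them bit-exactly.
#'
#' @param object A `modra_fit` from [train_model()] or a `modra_params`.
#' @param path Output file path.
#' @param cfg,gene_counts,drug_ids Required when `object` is bare
#'   parameters; taken from the fit otherwise.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path, cfg = NULL, gene_counts = NULL,
                            drug_ids = NULL) {
  if (inherits(object, "modra_fit")) {
    cfg <- object$model_config
    gene_counts <- object$gene_counts
    drug_ids <- object$drug_ids
    params <- object$params
  } else {
    params <- object
    if (is.null(cfg)) abort_modra("`cfg` is required for bare parameters")
  }
  payload <- list(
    format = "modra-checkpoint-1",
    model_config = unclass(cfg),
    gene_counts = gene_counts,
    drug_ids = drug_ids,
    train_config = if (inherits(object, "modra_fit")) unclass(object$train_config) else NULL,
    normalizer = if (inherits(object, "modra_fit") && !is.null(object$normalizer)) {
      lapply(object$normalizer, function(nz) lapply(nz, encode_array))
    } else NULL,
    params = encode_params(params)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file path.
#' @return A list with `params` (`modra_params`), `model_config`,
#'   `gene_counts`, `drug_ids`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "modra-checkpoint-1")) {
    abort_modra("%s is not a modra checkpoint", path)
  }
  mc <- payload$model_config
  cfg <- model_config(
    d1 = mc$d1, d2 = mc$d2, k = mc$k, d3 = mc$d3, d4 = mc$d4,
    n_drugs = mc$n_drugs, tau = mc$tau, dropout = mc$dropout,
    gamma_reg = mc$gamma_reg, gamma_align = mc$gamma_align,
    literal_batch_softmax = isTRUE(mc$literal_batch_softmax),
    detach_target = isTRUE(mc$detach_target), loss = mc$loss
  )
  tc <- payload$train_config
  tcfg <- if (is.null(tc)) NULL else train_config(
    epochs = tc$epochs, batch_size = tc$batch_size,
    lr_extractor = tc$lr_extractor, lr_predictor = tc$lr_predictor,
    folds = tc$folds, seed = tc$seed,
    use_alignment = isTRUE(tc$use_alignment),
    use_attention = isTRUE(tc$use_attention),
    views_enabled = as.integer(unlist(tc$views_enabled)),
    optimizer = tc$optimizer,
    normalize_inputs = isTRUE(tc$normalize_inputs)
  )
  normalizer <- if (is.null(payload$normalizer)) NULL else {
    lapply(payload$normalizer, function(nz) lapply(nz, decode_array))
  }
  list(
    params = decode_params(payload$params),
    model_config = cfg,
    gene_counts = as.integer(unlist(payload$gene_counts)),
    drug_ids = as.character(unlist(payload$drug_ids)),
    train_config = tcfg,
    normalizer = normalizer
  )
}

#' Rebuild a usable fit object from a loaded checkpoint
#'
#' @param path Checkpoint file path.
#' @return A `modra_fit` (with empty history) ready for [predict.modra_fit()]
#'   and the interpretability functions.
#' @export
checkpoint_to_fit <- function(path) {
  ck <- load_checkpoint(path)
  if (is.null(ck$train_config)) {
    abort_modra("checkpoint lacks a train_config; was it saved from a fit?")
  }
  structure(list(
    params = ck$params, history = empty_history(),
    model_config = ck$model_config, train_config = ck$train_config,
    gene_counts = ck$gene_counts, drug_ids = ck$drug_ids,
    view_kinds = omics_view_kinds(), normalizer = ck$normalizer
  ), class = "modra_fit")
}
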