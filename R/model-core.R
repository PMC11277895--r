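# Network operations. Internal tensor orientation follows the published
# equations: features x batch (columns are samples). User-facing matrices
# are samples x features and are transposed at the boundary.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# row-wise softmax with max subtraction
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# row-wise log-softmax with max subtraction
log_softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  s <- x - m
  s - log(rowSums(exp(s)))
}

#' Two-layer ReLU feature extractor for one omics view
#'
#' Computes `z = ReLU(W2 ReLU(W1 x + b1) + b2)` for a genes x batch input
#' slice. During training, inverted dropout at the configured rate is
#' applied after each ReLU.
#'
#' @param x Numeric genes x batch matrix (one view's inputs, transposed).
#' @param p Extractor parameter list with `W1`, `b1`, `W2`, `b2`.
#' @param dropout Dropout rate; only used when `training = TRUE`.
#' @param training Apply dropout? Default `FALSE`.
#' @return The d2 x batch embedding matrix (all entries nonnegative).
#' @export
feature_extract <- function(x, p, dropout = 0, training = FALSE) {
  extractor_forward(x, p, dropout, training)$z
}

extractor_forward <- function(x, p, dropout = 0, training = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (ncol(p$W1) != nrow(x)) {
    abort_modra("extractor expects %d input genes, got %d", ncol(p$W1), nrow(x))
  }
  a1 <- p$W1 %*% x + p$b1
  h1 <- relu(a1)
  m1 <- NULL
  if (training && dropout > 0) {
    m1 <- matrix((runif(length(h1)) >= dropout) / (1 - dropout), nrow(h1), ncol(h1))
    h1 <- h1 * m1
  }
  a2 <- p$W2 %*% h1 + p$b2
  z <- relu(a2)
  m2 <- NULL
  if (training && dropout > 0) {
    m2 <- matrix((runif(length(z)) >= dropout) / (1 - dropout), nrow(z), ncol(z))
    z <- z * m2
  }
  list(z = z, x = x, a1 = a1, h1 = h1, a2 = a2, m1 = m1, m2 = m2)
}

extractor_backward <- function(dz, cache, p) {
  if (!is.null(cache$m2)) dz <- dz * cache$m2
  da2 <- dz * (cache$a2 > 0)
  dW2 <- da2 %*% t(cache$h1)
  db2 <- rowSums(da2)
  dh1 <- crossprod(p$W2, da2)
  if (!is.null(cache$m1)) dh1 <- dh1 * cache$m1
  da1 <- dh1 * (cache$a1 > 0)
  dW1 <- da1 %*% t(cache$x)
  db1 <- rowSums(da1)
  dx <- crossprod(p$W1, da1)
  list(grad = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dx = dx)
}

#' Cross-view sample-similarity matrix
#'
#' `S[a, b]` is the inner product between sample a's embedding in view i and
#' sample b's embedding in view j: `S = t(z_i) %*% z_j`.
#'
#' @param z_i,z_j d2 x batch embedding matrices.
#' @return A batch x batch similarity matrix.
#' @export
sample_similarity <- function(z_i, z_j) {
  if (!identical(dim(z_i), dim(z_j))) abort_modra("embedding shapes differ")
  crossprod(z_i, z_j)
}

#' Soft alignment target from intra-view similarities
#'
#' `T = softmax((S11 + S22 + S33 + S44) / (4 tau))`, row-wise; every row is
#' a probability distribution over the batch. The temperature `tau`
#' regulates how peaked the target is.
#'
#' @param S_list List of the four intra-view similarity matrices.
#' @param tau Positive temperature.
#' @return A batch x batch row-stochastic matrix.
#' @export
alignment_target <- function(S_list, tau = 1) {
  if (tau <= 0) abort_modra("`tau` must be positive")
  softmax_rows(Reduce(`+`, S_list) / (4 * tau))
}

#' Contrastive latent-alignment loss
#'
#' Builds the soft target `T` from the four intra-view similarity matrices,
#' then sums, over the six unordered view pairs (i < j), the symmetrised
#' soft-label cross-entropy `0.5 * (CE(S_ij, T) + CE(S_ji, T))` where
#' `CE(S, T)` averages over batch rows the cross-entropy between the row of
#' `T` and the row-wise softmax of `S / tau`. By Gibbs' inequality the loss
#' is bounded below by six times the mean row entropy of `T`, attained when
#' all four embeddings coincide.
#'
#' @param z List of four d2 x batch embedding matrices.
#' @param tau Positive temperature.
#' @return A list with `loss`, the target `T`, the similarity matrices `S`
#'   (4 x 4 list, `S[[i]][[j]]`), class `alignment_state`.
#' @export
alignment_loss <- function(z, tau = 1) {
  if (length(z) < 2L) abort_modra("alignment needs at least two views")
  if (tau <= 0) abort_modra("`tau` must be positive")
  nv <- length(z)
  S <- lapply(seq_len(nv), function(i) {
    lapply(seq_len(nv), function(j) sample_similarity(z[[i]], z[[j]]))
  })
  Tmat <- alignment_target(lapply(seq_len(nv), function(i) S[[i]][[i]]), tau)
  bs <- nrow(Tmat)
  ce <- function(Smat) {
    L <- log_softmax_rows(Smat / tau)
    -sum(Tmat * L) / bs
  }
  loss <- 0
  for (i in seq_len(nv - 1L)) {
    for (j in seq(i + 1L, nv)) {
      loss <- loss + 0.5 * (ce(S[[i]][[j]]) + ce(S[[j]][[i]]))
    }
  }
  structure(list(loss = loss, target = Tmat, S = S), class = "alignment_state")
}

# mean row entropy of a row-stochastic matrix (0 log 0 = 0)
mean_row_entropy <- function(Tmat) {
  p <- Tmat[Tmat > 0]
  # rowwise -sum p log p, averaged; zero entries contribute nothing
  -sum(Tmat * log(pmax(Tmat, .Machine$double.xmin))) / nrow(Tmat)
}

# backward of alignment_loss wrt the four embeddings. With detach_target
# (default) the soft target T is treated as a constant per batch, the
# standard stop-gradient treatment for soft-target contrastive losses;
# otherwise the exact gradient of the composite function (through T and the
# intra-view similarities) is returned.
alignment_backward <- function(z, state, tau, detach_target = TRUE) {
  nv <- length(z)
  Tmat <- state$target
  bs <- nrow(Tmat)
  dS <- lapply(seq_len(nv), function(i) lapply(seq_len(nv), function(j) NULL))
  dT <- matrix(0, bs, bs)
  for (i in seq_len(nv - 1L)) {
    for (j in seq(i + 1L, nv)) {
      for (pair in list(c(i, j), c(j, i))) {
        Smat <- state$S[[pair[1L]]][[pair[2L]]]
        P <- softmax_rows(Smat / tau)
        L <- log_softmax_rows(Smat / tau)
        g <- (P - Tmat) / (2 * bs * tau)
        prev <- dS[[pair[1L]]][[pair[2L]]]
        dS[[pair[1L]]][[pair[2L]]] <- if (is.null(prev)) g else prev + g
        dT <- dT - L / (2 * bs)
      }
    }
  }
  if (!detach_target) {
    # target softmax backward, spread over the four intra-view similarities
    dA <- Tmat * (dT - rowSums(dT * Tmat))
    for (i in seq_len(nv)) dS[[i]][[i]] <- dA / (4 * tau)
  }
  dz <- lapply(z, function(m) matrix(0, nrow(m), ncol(m)))
  for (i in seq_len(nv)) {
    for (j in seq_len(nv)) {
      g <- dS[[i]][[j]]
      if (is.null(g)) next
      dz[[i]] <- dz[[i]] + z[[j]] %*% t(g)
      dz[[j]] <- dz[[j]] + z[[i]] %*% g
    }
  }
  dz
}

#' Bilinear affinity matrix between two views
#'
#' `F = tanh(t(z_j) %*% M %*% z_i)`; entries lie in (-1, 1).
#'
#' @param z_i,z_j d2 x batch embedding matrices.
#' @param M d2 x d2 learnable bilinear form.
#' @return A batch x batch affinity matrix.
#' @export
affinity_matrix <- function(z_i, z_j, M) {
  if (nrow(z_i) != ncol(M) || nrow(z_j) != nrow(M)) {
    abort_modra("affinity shapes do not match")
  }
  tanh(crossprod(z_j, M %*% z_i))
}

#' Co-attention fusion of the four view embeddings
#'
#' Each view aggregates the other views' projections through its affinity
#' matrices, `H_i = tanh(Wz_i z_i + sum_{j != i} Wz_j z_j F_ij)`, scores
#' them with `WH_i`, turns the scores into attention weights by softmax
#' (over the batch in literal mode, over the four views per sample
#' otherwise), rescales `z_i` by its weight and concatenates the four
#' reweighted embeddings along the feature axis.
#'
#' @param z List of four d2 x batch embedding matrices.
#' @param p Attention parameters (`M`, `Wz`, `WH`, see
#'   [init_model_params()]).
#' @param cfg A [model_config()] (uses `literal_batch_softmax`).
#' @return A (4 d2) x batch fused matrix. The attention weights are
#'   attached as attribute `"weights"` (4 x batch).
#' @export
coattention_fuse <- function(z, p, cfg) {
  fw <- coattention_forward(z, p, cfg)
  out <- fw$Zp
  attr(out, "weights") <- fw$A
  out
}

coattention_forward <- function(z, p, cfg) {
  nv <- length(z)
  bs <- ncol(z[[1L]])
  Fm <- lapply(seq_len(nv), function(i) lapply(seq_len(nv), function(j) NULL))
  for (i in seq_len(nv)) {
    for (j in seq_len(nv)) {
      if (i == j) next
      Fm[[i]][[j]] <- affinity_matrix(z[[i]], z[[j]], p$M[[i]][[j]])
    }
  }
  Q <- lapply(seq_len(nv), function(i) p$Wz[[i]] %*% z[[i]])
  P <- vector("list", nv)
  H <- vector("list", nv)
  scores <- matrix(0, nv, bs)
  for (i in seq_len(nv)) {
    acc <- Q[[i]]
    for (j in seq_len(nv)) {
      if (j == i) next
      acc <- acc + Q[[j]] %*% Fm[[i]][[j]]
    }
    P[[i]] <- acc
    H[[i]] <- tanh(acc)
    scores[i, ] <- p$WH[[i]] %*% H[[i]]
  }
  if (isTRUE(cfg$literal_batch_softmax)) {
    A <- t(apply(scores, 1L, function(s) {
      e <- exp(s - max(s)); e / sum(e)
    }))
    if (bs == 1L) A <- matrix(1, nv, 1L)  # apply() drops dims at bs = 1
  } else {
    A <- apply(scores, 2L, function(s) {
      e <- exp(s - max(s)); e / sum(e)
    })
    A <- matrix(A, nv, bs)
  }
  Zp <- do.call(rbind, lapply(seq_len(nv), function(i) {
    z[[i]] * rep(A[i, ], each = nrow(z[[i]]))
  }))
  list(Zp = Zp, A = A, H = H, P = P, Q = Q, Fm = Fm, scores = scores, z = z)
}

coattention_backward <- function(dZp, cache, p, cfg) {
  z <- cache$z
  nv <- length(z)
  d2 <- nrow(z[[1L]])
  bs <- ncol(z[[1L]])
  A <- cache$A
  dz <- lapply(z, function(m) matrix(0, d2, bs))
  dA <- matrix(0, nv, bs)
  for (i in seq_len(nv)) {
    rows <- ((i - 1L) * d2 + 1L):(i * d2)
    dzp <- dZp[rows, , drop = FALSE]
    dz[[i]] <- dz[[i]] + dzp * rep(A[i, ], each = d2)
    dA[i, ] <- colSums(dzp * z[[i]])
  }
  # softmax backward along the configured axis
  dscores <- matrix(0, nv, bs)
  if (isTRUE(cfg$literal_batch_softmax)) {
    for (i in seq_len(nv)) {
      a <- A[i, ]; g <- dA[i, ]
      dscores[i, ] <- a * (g - sum(g * a))
    }
  } else {
    for (s in seq_len(bs)) {
      a <- A[, s]; g <- dA[, s]
      dscores[, s] <- a * (g - sum(g * a))
    }
  }
  dWH <- vector("list", nv)
  dH <- vector("list", nv)
  for (i in seq_len(nv)) {
    dWH[[i]] <- matrix(dscores[i, ], 1L) %*% t(cache$H[[i]])
    dH[[i]] <- crossprod(p$WH[[i]], matrix(dscores[i, ], 1L))
  }
  dP <- lapply(seq_len(nv), function(i) dH[[i]] * (1 - cache$H[[i]]^2))
  dQ <- lapply(seq_len(nv), function(i) matrix(0, nrow(cache$Q[[i]]), bs))
  dM <- lapply(seq_len(nv), function(i) lapply(seq_len(nv), function(j) NULL))
  for (i in seq_len(nv)) {
    dQ[[i]] <- dQ[[i]] + dP[[i]]
    for (j in seq_len(nv)) {
      if (j == i) next
      dQ[[j]] <- dQ[[j]] + dP[[i]] %*% t(cache$Fm[[i]][[j]])
      dF <- crossprod(cache$Q[[j]], dP[[i]])
      dG <- dF * (1 - cache$Fm[[i]][[j]]^2)
      dM[[i]][[j]] <- z[[j]] %*% dG %*% t(z[[i]])
      dz[[i]] <- dz[[i]] + crossprod(p$M[[i]][[j]], z[[j]]) %*% dG
      dz[[j]] <- dz[[j]] + p$M[[i]][[j]] %*% z[[i]] %*% t(dG)
    }
  }
  dWz <- vector("list", nv)
  for (i in seq_len(nv)) {
    dWz[[i]] <- dQ[[i]] %*% t(z[[i]])
    dz[[i]] <- dz[[i]] + crossprod(p$Wz[[i]], dQ[[i]])
  }
  list(grad = list(M = dM, Wz = dWz, WH = dWH), dz = dz)
}

#' Multi-drug regression head
#'
#' `Pred = W5 ReLU(W4 ReLU(W3 Z' + b3) + b4) + b5`; the output is linear
#' because log(IC50) responses may be negative.
#'
#' @param Zp (4 d2) x batch fused feature matrix.
#' @param p Predictor parameters (`W3`..`W5`, `b3`..`b5`).
#' @return A drugs x batch prediction matrix.
#' @export
predict_head <- function(Zp, p) {
  predictor_forward(Zp, p)$pred
}

predictor_forward <- function(Zp, p) {
  if (ncol(p$W3) != nrow(Zp)) {
    abort_modra("predictor expects %d fused features, got %d", ncol(p$W3), nrow(Zp))
  }
  a3 <- p$W3 %*% Zp + p$b3
  h3 <- relu(a3)
  a4 <- p$W4 %*% h3 + p$b4
  h4 <- relu(a4)
  pred <- p$W5 %*% h4 + p$b5
  list(pred = pred, Zp = Zp, a3 = a3, h3 = h3, a4 = a4, h4 = h4)
}

predictor_backward <- function(dpred, cache, p) {
  dW5 <- dpred %*% t(cache$h4)
  db5 <- rowSums(dpred)
  dh4 <- crossprod(p$W5, dpred)
  da4 <- dh4 * (cache$a4 > 0)
  dW4 <- da4 %*% t(cache$h3)
  db4 <- rowSums(da4)
  dh3 <- crossprod(p$W4, da4)
  da3 <- dh3 * (cache$a3 > 0)
  dW3 <- da3 %*% t(cache$Zp)
  db3 <- rowSums(da3)
  dZp <- crossprod(p$W3, da3)
  list(grad = list(W3 = dW3, b3 = db3, W4 = dW4, b4 = db4, W5 = dW5, b5 = db5),
       dZp = dZp)
}

#' Masked regression loss
#'
#' Mean squared (or absolute) error over the non-missing response entries;
#' missing entries contribute to neither the sum nor the count.
#'
#' @param pred,y Drugs x batch matrices of predicted and observed responses.
#' @param mask Logical drugs x batch matrix, `TRUE` = missing.
#' @param loss `"mse"` (default) or `"mae"`.
#' @return A nonnegative scalar.
#' @export
regression_loss <- function(pred, y, mask = NULL, loss = c("mse", "mae")) {
  loss <- match.arg(loss)
  if (!identical(dim(pred), dim(y))) abort_modra("prediction/response shapes differ")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(y), ncol(y))
  keep <- !mask
  n <- sum(keep)
  if (n == 0L) abort_modra("no observed response entries")
  r <- (pred - y)[keep]
  if (loss == "mse") mean(r^2) else mean(abs(r))
}

regression_loss_backward <- function(pred, y, mask, loss = "mse") {
  keep <- !mask
  n <- sum(keep)
  r <- (pred - y) * keep
  r[is.na(r)] <- 0
  if (loss == "mse") 2 * r / n else sign(r) / n
}

#' Weighted total loss
#'
#' `L_total = gamma_reg * L_reg + gamma_align * L_align`, the 1:1 weighting
#' by default.
#'
#' @param loss_reg,loss_align Scalar loss values.
#' @param gamma_reg,gamma_align Nonnegative weights.
#' @return A scalar.
#' @export
total_loss <- function(loss_reg, loss_align, gamma_reg = 1, gamma_align = 1) {
  gamma_reg * loss_reg + gamma_align * loss_align
}

#' Full forward pass over a batch
#'
#' Extracts each view's embedding, optionally computes the alignment state,
#' fuses by co-attention (or plain concatenation when `use_attention =
#' FALSE`) and applies the regression head. When `masked_view` is given,
#' that view's input slice is replaced by zeros before extraction — the
#' omics-masking protocol of the importance analysis.
#'
#' @param x_list List of four genes x batch input matrices (one per view).
#' @param params `modra_params`.
#' @param cfg A [model_config()].
#' @param training Apply dropout and (by default) compute alignment?
#' @param masked_view Optional view index in 1:4 to zero out.
#' @param use_attention Use the co-attention fusion (default `TRUE`)?
#' @param compute_alignment Compute the alignment state? Defaults to
#'   `training`.
#' @return List with `pred` (drugs x batch), `z` (list of embeddings),
#'   `alignment` (an `alignment_state` or `NULL`) and internal caches.
#' @export
model_forward <- function(x_list, params, cfg, training = FALSE,
                          masked_view = NULL, use_attention = TRUE,
                          compute_alignment = training) {
  if (!is.null(masked_view)) {
    if (!(masked_view %in% seq_along(x_list))) abort_modra("invalid view index")
    x_list[[masked_view]] <- matrix(0, nrow(x_list[[masked_view]]),
                                    ncol(x_list[[masked_view]]))
  }
  ex <- lapply(seq_along(x_list), function(i) {
    extractor_forward(x_list[[i]], params$extractor[[i]],
                      dropout = cfg$dropout, training = training)
  })
  z <- lapply(ex, `[[`, "z")
  align <- if (compute_alignment) alignment_loss(z, cfg$tau) else NULL
  if (use_attention) {
    att <- coattention_forward(z, params$attention, cfg)
    Zp <- att$Zp
  } else {
    att <- NULL
    Zp <- do.call(rbind, z)
  }
  pf <- predictor_forward(Zp, params$predictor)
  list(pred = pf$pred, z = z, alignment = align,
       cache = list(extract = ex, attention = att, predictor = pf,
                    use_attention = use_attention))
}
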