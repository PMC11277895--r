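# Index-by-index reference implementations of every tensor operation,
# written with explicit loops so they share no code path with the package.

relu_scalar <- function(x) max(x, 0)

oracle_feature_extract <- function(x, p) {
  d1 <- nrow(p$W1); d2 <- nrow(p$W2); bs <- ncol(x); g <- nrow(x)
  z <- matrix(0, d2, bs)
  for (s in seq_len(bs)) {
    h1 <- numeric(d1)
    for (a in seq_len(d1)) {
      acc <- p$b1[a]
      for (gg in seq_len(g)) acc <- acc + p$W1[a, gg] * x[gg, s]
      h1[a] <- relu_scalar(acc)
    }
    for (b in seq_len(d2)) {
      acc <- p$b2[b]
      for (a in seq_len(d1)) acc <- acc + p$W2[b, a] * h1[a]
      z[b, s] <- relu_scalar(acc)
    }
  }
  z
}

oracle_similarity <- function(z_i, z_j) {
  bs <- ncol(z_i)
  S <- matrix(0, bs, bs)
  for (a in seq_len(bs)) {
    for (b in seq_len(bs)) {
      S[a, b] <- sum(z_i[, a] * z_j[, b])
    }
  }
  S
}

oracle_affinity <- function(z_i, z_j, M) {
  bs <- ncol(z_i)
  Fm <- matrix(0, bs, bs)
  for (a in seq_len(bs)) {
    for (b in seq_len(bs)) {
      acc <- 0
      for (p in seq_len(nrow(M))) {
        for (q in seq_len(ncol(M))) {
          acc <- acc + z_j[p, a] * M[p, q] * z_i[q, b]
        }
      }
      Fm[a, b] <- tanh(acc)
    }
  }
  Fm
}

oracle_softmax_vec <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# full co-attention fusion, looped; literal controls the softmax axis
oracle_coattention <- function(z, p, literal) {
  nv <- length(z); d2 <- nrow(z[[1]]); bs <- ncol(z[[1]])
  Fm <- vector("list", nv)
  for (i in seq_len(nv)) {
    Fm[[i]] <- vector("list", nv)
    for (j in seq_len(nv)) {
      if (i != j) Fm[[i]][[j]] <- oracle_affinity(z[[i]], z[[j]], p$M[[i]][[j]])
    }
  }
  scores <- matrix(0, nv, bs)
  for (i in seq_len(nv)) {
    H <- matrix(0, nrow(p$Wz[[i]]), bs)
    for (s in seq_len(bs)) {
      for (kk in seq_len(nrow(p$Wz[[i]]))) {
        acc <- sum(p$Wz[[i]][kk, ] * z[[i]][, s])
        for (j in seq_len(nv)) {
          if (j == i) next
          # (Wz_j z_j F_ij)[kk, s] = sum_b (Wz_j z_j)[kk, b] F_ij[b, s]
          for (b in seq_len(bs)) {
            acc <- acc + sum(p$Wz[[j]][kk, ] * z[[j]][, b]) * Fm[[i]][[j]][b, s]
          }
        }
        H[kk, s] <- tanh(acc)
      }
    }
    for (s in seq_len(bs)) scores[i, s] <- sum(p$WH[[i]][1, ] * H[, s])
  }
  A <- matrix(0, nv, bs)
  if (literal) {
    for (i in seq_len(nv)) A[i, ] <- oracle_softmax_vec(scores[i, ])
  } else {
    for (s in seq_len(bs)) A[, s] <- oracle_softmax_vec(scores[, s])
  }
  Zp <- matrix(0, nv * d2, bs)
  for (i in seq_len(nv)) {
    for (s in seq_len(bs)) {
      Zp[((i - 1) * d2 + 1):(i * d2), s] <- A[i, s] * z[[i]][, s]
    }
  }
  Zp
}

oracle_predict_head <- function(Zp, p) {
  d3 <- nrow(p$W3); d4 <- nrow(p$W4); D <- nrow(p$W5); bs <- ncol(Zp)
  pred <- matrix(0, D, bs)
  for (s in seq_len(bs)) {
    h3 <- numeric(d3)
    for (a in seq_len(d3)) h3[a] <- relu_scalar(sum(p$W3[a, ] * Zp[, s]) + p$b3[a])
    h4 <- numeric(d4)
    for (a in seq_len(d4)) h4[a] <- relu_scalar(sum(p$W4[a, ] * h3) + p$b4[a])
    for (d in seq_len(D)) pred[d, s] <- sum(p$W5[d, ] * h4) + p$b5[d]
  }
  pred
}

# brute-force AUROC: enumerate positive-negative pairs, ties count 1/2
oracle_auroc <- function(truth, scores) {
  pos <- which(truth == 1)
  neg <- which(truth == 0)
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (a in pos) {
    for (b in neg) {
      if (scores[a] > scores[b]) total <- total + 1
      else if (scores[a] == scores[b]) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

# exact hypergeometric upper tail by combinatorial sum
oracle_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}

# random small parameter set + embeddings for oracle comparisons
random_instance <- function(seed, g = NULL, bs = NULL, d2 = NULL, k = NULL) {
  set.seed(seed)
  if (is.null(bs)) bs <- sample(1:4, 1)
  if (is.null(d2)) d2 <- sample(2:6, 1)
  if (is.null(k)) k <- sample(2:4, 1)
  if (is.null(g)) g <- sample(3:7, 4, replace = TRUE)
  cfg <- model_config(d1 = 5, d2 = d2, k = k, d3 = 6, d4 = 4, n_drugs = 3,
                      dropout = 0, tau = runif(1, 0.5, 2))
  params <- init_model_params(g, cfg, seed = seed + 1000)
  x <- lapply(g, function(gg) matrix(rnorm(gg * bs), gg, bs))
  z <- lapply(1:4, function(i) matrix(abs(rnorm(d2 * bs)), d2, bs))
  list(cfg = cfg, params = params, x = x, z = z, bs = bs, d2 = d2, k = k, g = g)
}
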