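#' Configuration for the synthetic multi-omics generator
#'
#' The generator draws latent sample factors `U` (n x r, standard normal)
#' shared by all informative views. Each informative view i observes
#' `U %*% B_i + E_i` with fixed standard-normal loadings `B_i` and Gaussian
#' noise `E_i` (sd `view_noise_sd`), then maps the raw values to the view's
#' admissible range: mutation = indicator(raw > 0), methylation =
#' logistic(raw), CNV = round(raw), expression = softplus(raw).
#' Non-informative views are pure noise put through the same maps. Drug
#' responses are `U %*% W_y + eps` with `eps` sd `response_noise_sd`, so a
#' closed-form best-attainable R-squared exists per drug:
#' `||w_d||^2 / (||w_d||^2 + response_noise_sd^2)`.
#'
#' @param n_samples Number of samples (default 600).
#' @param genes_per_view Integer vector of length 4: features per view
#'   (mutation, cnv, methylation, expression). Default 200 each.
#' @param latent_rank Rank r of the shared latent structure (default 5).
#' @param informative_views Subset of 1:4 whose views carry the latent
#'   signal; the rest are pure noise. Default all four.
#' @param response_noise_sd Sd of the additive response noise (default 0.5).
#' @param view_noise_sd Sd of the additive view noise before the range map
#'   (default 0.5).
#' @param missing_rate Fraction of view entries planted as missing
#'   (default 0).
#' @param n_drugs Number of drugs D (default 31).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 600, genes_per_view = rep(200L, 4),
                              latent_rank = 5, informative_views = 1:4,
                              response_noise_sd = 0.5, view_noise_sd = 0.5,
                              missing_rate = 0, n_drugs = 31L, seed = 0L) {
  genes_per_view <- as.integer(genes_per_view)
  if (length(genes_per_view) != 4L || any(genes_per_view < 1L)) {
    abort_modra("`genes_per_view` must be 4 positive integers")
  }
  if (latent_rank < 1 || latent_rank > min(genes_per_view)) {
    abort_modra("`latent_rank` must lie in [1, min(genes_per_view)]")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort_modra("`missing_rate` must lie in [0, 1)")
  if (response_noise_sd < 0) abort_modra("`response_noise_sd` must be nonnegative")
  if (n_samples < 1 || n_drugs < 1) abort_modra("need at least one sample and one drug")
  if (!all(informative_views %in% 1:4) || length(informative_views) < 1) {
    abort_modra("`informative_views` must be a nonempty subset of 1:4")
  }
  structure(list(
    n_samples = as.integer(n_samples), genes_per_view = genes_per_view,
    latent_rank = as.integer(latent_rank),
    informative_views = sort(unique(as.integer(informative_views))),
    response_noise_sd = response_noise_sd, view_noise_sd = view_noise_sd,
    missing_rate = missing_rate, n_drugs = as.integer(n_drugs),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Generate a synthetic multi-omics dataset with shared latent structure
#'
#' See [simulation_config()] for the generative model. The latent factors
#' `U`, the per-view loadings `B` and the response loadings `W_y` are
#' attached as attributes `"latent"`, `"loadings"` and `"response_loadings"`
#' for oracle checks (loadings of non-informative views are `NULL`).
#'
#' @param cfg A [simulation_config()].
#' @return A [multiomics_dataset()]; views may contain missing entries when
#'   `missing_rate > 0`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_samples
  r <- cfg$latent_rank
  ids <- sprintf("S%04d", seq_len(n))
  U <- matrix(rnorm(n * r), n, r)
  kinds <- omics_view_kinds()
  prefixes <- c(mutation = "MUT", cnv = "CNV", methylation = "MET", expression = "EXP")
  loadings <- vector("list", 4L)
  names(loadings) <- kinds
  views <- vector("list", 4L)
  for (i in 1:4) {
    g <- cfg$genes_per_view[i]
    kind <- kinds[i]
    if (i %in% cfg$informative_views) {
      B <- matrix(rnorm(r * g), r, g)
      loadings[[i]] <- B
      raw <- U %*% B + matrix(rnorm(n * g, sd = cfg$view_noise_sd), n, g)
    } else {
      raw <- matrix(rnorm(n * g), n, g)
    }
    vals <- switch(kind,
      mutation    = (raw > 0) * 1,
      cnv         = round(raw),
      methylation = stats::plogis(raw),
      expression  = softplus(raw)
    )
    dimnames(vals) <- list(ids, sprintf("%s_G%04d", prefixes[kind], seq_len(g)))
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(n * g) < cfg$missing_rate, n, g)
      vals[miss] <- NA_real_
    }
    views[[i]] <- omics_matrix(vals, kind)
  }
  W_y <- matrix(rnorm(r * cfg$n_drugs), r, cfg$n_drugs)
  Y <- U %*% W_y + matrix(rnorm(n * cfg$n_drugs, sd = cfg$response_noise_sd),
                          n, cfg$n_drugs)
  dimnames(Y) <- list(ids, sprintf("drug_%02d", seq_len(cfg$n_drugs)))
  data <- multiomics_dataset(views, response_matrix(Y))
  attr(data, "latent") <- U
  attr(data, "loadings") <- loadings
  attr(data, "response_loadings") <- W_y
  attr(data, "config") <- cfg
  data
}

# save/restore the global RNG state so generation is a pure function of seed
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Hand-sized raw dataset exercising every preprocessing rule
#'
#' Six samples, at most ten features per view. The mutation view contains
#' exactly one sample with more than 30% missing entries (4 of 10), the
#' expression view contains exactly one all-zero gene, and scattered single
#' missing cells are left for mean imputation. Expected post-preprocessing
#' counts are attached as the `expected` element.
#'
#' @return A list with `views` (four raw [omics_matrix()]), `response`
#'   (a [response_matrix()]) and `expected` (named list of the counts the
#'   preprocessing pipeline must produce: 5 samples; features 10/8/8/9).
#' @export
make_toy_fixture <- function() {
  ids <- sprintf("S%02d", 1:6)
  # mutation: 10 genes; sample S02 has 4/10 missing (40% > 30% -> dropped);
  # S03 has exactly 3/10 missing (30%, kept at the boundary)
  mut <- matrix(rep(c(0, 1), length.out = 60), 6, 10,
                dimnames = list(ids, sprintf("MUT_G%02d", 1:10)))
  mut["S02", 1:4] <- NA
  mut["S03", 1:3] <- NA
  # cnv: 8 genes, one imputable missing cell
  cnv <- matrix(rep(c(-1, 0, 2, 1), length.out = 48), 6, 8,
                dimnames = list(ids, sprintf("CNV_G%02d", 1:8)))
  cnv["S01", 2] <- NA
  # methylation: 8 CpG fractions, one imputable missing cell
  met <- matrix(rep(seq(0.1, 0.9, by = 0.1), length.out = 48), 6, 8,
                dimnames = list(ids, sprintf("MET_G%02d", 1:8)))
  met["S04", 5] <- NA
  # expression: 10 genes, gene 3 all-zero (dropped), one missing cell
  expr <- matrix(rep(c(1.5, 0.2, 3.1, 0.4), length.out = 60), 6, 10,
                 dimnames = list(ids, sprintf("EXP_G%02d", 1:10)))
  expr[, 3] <- 0
  expr["S05", 7] <- NA
  resp <- matrix(c(-2.1, 0.4, 1.3, -0.5, 2.2, -1.7,
                   0.9, -3.0, 0.1, 1.8, -0.6, 0.3,
                   -1.2, 2.5, -0.8, 0.0, 1.1, -2.4), 6, 3,
                 dimnames = list(ids, c("drug_A", "drug_B", "drug_C")))
  list(
    views = list(
      omics_matrix(mut, "mutation"),
      omics_matrix(cnv, "cnv"),
      omics_matrix(met, "methylation"),
      omics_matrix(expr, "expression")
    ),
    response = response_matrix(resp),
    expected = list(
      n_samples = 5L,
      dropped_sample = "S02",
      n_features = c(mutation = 10L, cnv = 8L, methylation = 8L, expression = 9L),
      dropped_feature = "EXP_G03"
    )
  )
}
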