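# Small data builders shared across test files.

small_omics <- function(values, kind = "expression") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("G%02d", seq_len(ncol(values)))
  }
  omics_matrix(values, kind)
}

# a fast, tiny model configuration used wherever training speed matters
tiny_mcfg <- function(n_drugs = 3, ...) {
  model_config(d1 = 16, d2 = 8, k = 4, d3 = 12, d4 = 8, n_drugs = n_drugs,
               literal_batch_softmax = FALSE, ...)
}

tiny_dataset <- function(seed = 0, n = 40, n_drugs = 3) {
  generate_dataset(simulation_config(
    n_samples = n, genes_per_view = c(12, 10, 11, 13), latent_rank = 3,
    n_drugs = n_drugs, seed = seed
  ))
}

# random raw views (with missingness) + response, for preprocessing props
random_raw_views <- function(seed, n = 8, g = 6, miss = 0.15) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n))
  kinds <- c("mutation", "cnv", "methylation", "expression")
  views <- lapply(kinds, function(kind) {
    vals <- switch(kind,
      mutation = matrix(rbinom(n * g, 1, 0.4), n, g),
      cnv = matrix(sample(-2:3, n * g, TRUE), n, g),
      methylation = matrix(runif(n * g), n, g),
      expression = matrix(abs(rnorm(n * g)) + 0.1, n, g)
    )
    vals[matrix(runif(n * g) < miss, n, g)] <- NA
    # keep at least one observed nonzero per column so impute/drop succeed
    vals[1, ] <- switch(kind, mutation = 1, cnv = 1,
                        methylation = 0.5, expression = 1)
    dimnames(vals) <- list(ids, sprintf("%s_G%02d", toupper(substr(kind, 1, 3)), seq_len(g)))
    omics_matrix(vals, kind)
  })
  resp <- matrix(rnorm(n * 2), n, 2, dimnames = list(ids, c("dA", "dB")))
  list(views = views, response = response_matrix(resp))
}
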