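# Compact sim_truth constructor for focused tests.

make_truth <- function(freqs = c(A = 0.3, B = 0.4),
                       theta = NULL,
                       n_genes = 5,
                       effects = NULL,
                       intercepts = NULL,
                       loadings = NULL,
                       noise_sd = 1,
                       block_betas = list(),
                       censor_rate = 0.3,
                       frailty_sd = 0,
                       seed = 1L, ...) {
  m <- length(freqs)
  genes <- paste0("g", seq_len(n_genes))
  if (is.null(effects)) {
    effects <- matrix(0, m, n_genes, dimnames = list(names(freqs), genes))
  } else {
    dimnames(effects) <- list(names(freqs), genes)
  }
  if (is.null(intercepts)) intercepts <- rep(0, n_genes)
  if (is.null(loadings)) loadings <- matrix(0, 0, n_genes,
                                            dimnames = list(NULL, genes))
  else colnames(loadings) <- genes
  sim_truth(
    mutation_freqs = freqs,
    pair_log_odds = theta,
    effect_matrix = effects,
    gene_intercepts = intercepts,
    latent_loadings = loadings,
    noise_sd = noise_sd,
    block_betas = block_betas,
    censor_rate = censor_rate,
    frailty_sd = frailty_sd,
    seed = seed, ...
  )
}

# cohort-level shortcut used by several files
small_cohort <- function(n = 120, n_genes = 60, seed = 42L) {
  simulate_cohort(n, default_truth(n_genes = n_genes, seed = seed))
}
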