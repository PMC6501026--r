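#' Generate log-scale expression as additive mutation effects plus latent
#' factors plus noise
#'
#' Implements the additive model under which the expression profile of a
#' tumor carrying several driver mutations is the sum of the shifts
#' attributable to each mutation: for gene g and sample i,
#' \deqn{y_{gi} = a_g + \sum_m x_{im}\beta_{mg} + \sum_f z_{if}\lambda_{fg} + e_{gi}}
#' with standard-normal latent factor scores `z` and Gaussian noise with
#' per-gene standard deviation `truth$noise_sd`.  Expression is generated
#' directly on log scale; there is no count layer.
#'
#' @param mutations binary mutation matrix (samples x drivers), as produced
#'   by [generate_mutations()].
#' @param truth a [sim_truth()] object whose `effect_matrix` has one row per
#'   driver in `mutations`.
#' @return Expression matrix (genes x samples) with attribute
#'   `latent_scores` (samples x factors) recording the realized factor
#'   scores.
#' @export
generate_expression <- function(mutations, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  .check_binary_matrix(mutations)
  m <- length(truth$mutation_freqs)
  if (ncol(mutations) != m || !identical(colnames(mutations),
                                         names(truth$mutation_freqs))) {
    stop("mutation matrix columns do not match the drivers of 'truth'",
         call. = FALSE)
  }
  n <- nrow(mutations)
  n_genes <- ncol(truth$effect_matrix)
  genes <- colnames(truth$effect_matrix) %||% sprintf("g%04d", seq_len(n_genes))

  shifts <- mutations %*% truth$effect_matrix            # samples x genes
  .with_seed(.stream_seed(truth$seed, "expression"), {
    z <- matrix(stats::rnorm(n * truth$n_latent), n, truth$n_latent)
    noise <- matrix(stats::rnorm(n * n_genes), n, n_genes)
  })
  noise <- sweep(noise, 2, truth$noise_sd, `*`)
  lat <- if (truth$n_latent > 0) z %*% truth$latent_loadings else 0
  y <- t(shifts + lat + noise) + truth$gene_intercepts    # genes x samples
  dimnames(y) <- list(genes, rownames(mutations))
  attr(y, "latent_scores") <- z
  y
}
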