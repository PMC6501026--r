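#' Simulate a complete synthetic multi-omic cohort
#'
#' Runs the three generator stages — pairwise auto-logistic mutations,
#' additive-plus-latent-factor expression, and clinical covariates with
#' Weibull proportional-hazards survival — and bundles their outputs with
#' the generating `sim_truth`, so every downstream analysis stage can be
#' checked against known parameters.
#'
#' @param n_samples cohort size.
#' @param truth a [sim_truth()]; defaults to [default_truth()].
#' @return Object of class `synthetic_cohort`: list with `mutations`
#'   (samples x drivers), `expression` (genes x samples), `clinical`
#'   (data.frame) and `truth`.
#' @export
#' @examples
#' coh <- simulate_cohort(100, default_truth(n_genes = 50))
#' coh
simulate_cohort <- function(n_samples, truth = default_truth()) {
  mut <- generate_mutations(n_samples, truth)
  expr <- generate_expression(mut, truth)
  clin <- generate_clinical_and_survival(mut, expr, truth)
  structure(list(mutations = mut, expression = expr, clinical = clin,
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic multi-omic cohort\n")
  cat(sprintf("  samples: %d, drivers: %d, genes: %d\n",
              nrow(x$mutations), ncol(x$mutations), nrow(x$expression)))
  rc <- attr(x$clinical, "realized_censoring")
  cat(sprintf("  events: OS %d/%d, RFS %d/%d (censoring %.0f%% / %.0f%%)\n",
              sum(x$clinical$os_event), nrow(x$clinical),
              sum(x$clinical$rfs_event), nrow(x$clinical),
              100 * rc["os"], 100 * rc["rfs"]))
  cat(sprintf("  seed: %d\n", x$truth$seed))
  invisible(x)
}

#' Write a cohort to the standard pipeline TSVs plus a truth file
#'
#' Emits `mutations.tsv` (samples x drivers), `expression.tsv`
#' (genes x samples), `clinical.tsv`, and `truth.json` holding all
#' generator parameters.  Re-reading the TSVs with the package readers
#' reproduces the matrices exactly; re-running with the same seed produces
#' byte-identical files.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("mutations.tsv", "expression.tsv",
                            "clinical.tsv", "truth.json"))
  .write_matrix_tsv(cohort$mutations, paths[1], id_col = "sample")
  .write_matrix_tsv(cohort$expression, paths[2], id_col = "gene")
  utils::write.table(cohort$clinical, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- cohort$truth
  tr_out <- list(
    mutation_freqs = as.list(tr$mutation_freqs),
    pair_log_odds = tr$pair_log_odds,
    n_latent = tr$n_latent,
    noise_sd = tr$noise_sd,
    block_betas = tr$block_betas,
    baseline_shape = tr$baseline_shape,
    baseline_scale = tr$baseline_scale,
    censor_rate = tr$censor_rate,
    frailty_sd = tr$frailty_sd,
    rfs_scale = tr$rfs_scale,
    seed = tr$seed
  )
  jsonlite::write_json(tr_out, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' @noRd
.write_matrix_tsv <- function(x, path, id_col = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
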