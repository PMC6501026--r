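# Empirical-Bayes variance moderation and moderated F / t statistics.
#
# The per-gene residual variances s2_g (each on d residual degrees of
# freedom) are modelled as draws from a scaled inverse chi-square prior
# with d0 degrees of freedom and scale s0^2.  The prior is estimated by
# matching the first two moments of log s2_g, whose theoretical mean and
# variance under the hierarchy involve digamma/trigamma terms; the
# posterior variance is the precision-weighted blend
#   s2_post = (d0 * s0^2 + d * s2_g) / (d0 + d),
# and the moderated F on the mutation block uses s2_post in its denominator
# with augmented denominator degrees of freedom d0 + d.

#' @noRd
.trigamma_inverse <- function(x) {
  # Solve trigamma(y) = x for y > 0 by Newton iteration on a stable scale.
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' @noRd
.fit_variance_prior <- function(s2, d) {
  # Moment matching on z = log(s2): under the hierarchy,
  #   E z = log s0^2 + [digamma(d/2) - log(d/2)] - [digamma(d0/2) - log(d0/2)]
  #   Var z = trigamma(d/2) + trigamma(d0/2)
  z <- log(s2)
  evar <- stats::var(z) - trigamma(d / 2)
  if (evar <= 0) {
    # no excess dispersion: infinite prior df, complete shrinkage
    d0 <- Inf
    s0_2 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated statistics for the per-gene fits
#'
#' Populates the moderated fields of a [fit_gene_models()] result: the
#' scaled inverse chi-square variance prior estimated across the gene
#' ensemble, posterior (moderated) residual variances, the moderated
#' omnibus F over the mutation-coefficient block with
#' Benjamini-Hochberg-adjusted q-values, and per-coefficient moderated t
#' statistics with q-values adjusted over the full gene-by-mutation grid
#' (used by [target_genes()]).
#'
#' In the limit of zero prior degrees of freedom the moderated F equals the
#' classical F exactly; `prior_df` can force that limit or any fixed prior.
#'
#' @param fits a `gene_fits` (>= 10 genes, so the ensemble supports prior
#'   estimation).
#' @param prior_df optional: force the prior degrees of freedom instead of
#'   estimating them (`0` reproduces classical statistics, `Inf` complete
#'   shrinkage).
#' @return The `gene_fits` with element `moderated`: list with `d0`,
#'   `s0_2`, `s2_post`, `F`, `p`, `q`, `coef_t`, `coef_p`, `coef_q`,
#'   `df1`, `df2`.
#' @export
moderate_statistics <- function(fits, prior_df = NULL) {
  stopifnot(inherits(fits, "gene_fits"))
  g <- length(fits$genes)
  if (g < 10) stop("prior estimation needs at least 10 genes", call. = FALSE)
  d <- fits$df_residual
  s2 <- fits$sigma2

  if (is.null(prior_df)) {
    if (stats::var(log(s2)) < 1e-12) {
      warning("all residual variances identical; falling back to ",
              "unmoderated statistics", call. = FALSE)
      prior <- list(d0 = 0, s0_2 = mean(s2))
    } else {
      prior <- .fit_variance_prior(s2, d)
    }
  } else {
    stopifnot(prior_df >= 0)
    s0_2 <- if (is.finite(prior_df) && prior_df > 0) {
      exp(mean(log(s2)) - digamma(d / 2) + log(d / 2) +
            digamma(prior_df / 2) - log(prior_df / 2))
    } else if (is.infinite(prior_df)) {
      exp(mean(log(s2)) - digamma(d / 2) + log(d / 2))
    } else mean(s2)
    prior <- list(d0 = prior_df, s0_2 = s0_2)
  }
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) rep(prior$s0_2, g) else {
    (d0 * prior$s0_2 + d * s2) / (d0 + d)
  }

  k <- length(fits$mutation_cols)
  ss_mut <- fits$rss_reduced - fits$rss
  Fstat <- (ss_mut / k) / s2_post
  df2 <- d0 + d
  p <- stats::pf(Fstat, k, df2, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")

  # per-coefficient moderated t over the mutation block
  su <- fits$stdev_unscaled[fits$mutation_cols]
  B <- fits$coefficients[, fits$mutation_cols, drop = FALSE]
  se <- sqrt(s2_post) %o% su
  tt <- B / se
  tp <- 2 * stats::pt(abs(tt), df2, lower.tail = FALSE)
  tq <- matrix(stats::p.adjust(tp, method = "BH"), nrow(tp), ncol(tp),
               dimnames = dimnames(tp))

  fits$moderated <- list(d0 = d0, s0_2 = prior$s0_2, s2_post = s2_post,
                         F = Fstat, p = p, q = q,
                         coef_t = tt, coef_p = tp, coef_q = tq,
                         df1 = k, df2 = df2)
  fits
}

#' Mutation-centric target-gene set
#'
#' Genes whose expression is significantly associated with one driver
#' mutation: per-coefficient moderated t, Benjamini-Hochberg adjusted over
#' the full gene-by-mutation grid, thresholded at `q_threshold`, signed by
#' the fitted log-fold-change coefficient.
#'
#' @param fits a moderated `gene_fits` (see [moderate_statistics()]).
#' @param mutation driver identifier.
#' @param q_threshold FDR threshold (default 0.01).
#' @return Object of class `target_gene_set`: `data.frame` with `gene`,
#'   `log_fc`, `q`; attributes `mutation`, `q_threshold`,
#'   `universe_size`.
#' @export
target_genes <- function(fits, mutation, q_threshold = 0.01) {
  stopifnot(inherits(fits, "gene_fits"))
  if (is.null(fits$moderated)) {
    stop("run moderate_statistics() first", call. = FALSE)
  }
  if (!mutation %in% fits$mutation_cols) {
    stop(sprintf("unknown mutation '%s'", mutation), call. = FALSE)
  }
  q <- fits$moderated$coef_q[, mutation]
  sel <- which(q < q_threshold)
  out <- data.frame(
    gene = fits$genes[sel],
    log_fc = unname(fits$coefficients[sel, mutation]),
    q = unname(q[sel]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$q, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("target_gene_set", "data.frame"),
            mutation = mutation, q_threshold = q_threshold,
            universe_size = length(fits$genes))
}

#' @export
print.target_gene_set <- function(x, ...) {
  cat(sprintf("Target genes of %s: %d of %d (q < %g)\n",
              attr(x, "mutation"), nrow(x), attr(x, "universe_size"),
              attr(x, "q_threshold")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}
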