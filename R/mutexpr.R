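# Per-gene additive linear models of expression on driver-mutation status.
#
# One shared design matrix (intercept + mutation indicators + confounders)
# is QR-factored once and applied to every gene, in the spirit of the
# large-scale linear modelling used for differential expression.

#' @noRd
.confounder_matrix <- function(confounders, n) {
  if (is.null(confounders)) {
    return(matrix(0, n, 0))
  }
  stopifnot(is.data.frame(confounders), nrow(confounders) == n)
  mm <- stats::model.matrix(~., data = confounders)
  mm[, -1, drop = FALSE]
}

#' Fit the additive mutation-expression model to every gene
#'
#' For each gene g, ordinary least squares of log expression on a shared
#' design `intercept + mutation indicators + confounders`:
#' \deqn{y_g = a_g + X_{mut}\beta_g + X_{conf}\gamma_g + e_g.}
#' The model is additive in mutations: a tumor carrying several drivers is
#' modelled as the sum of their individual expression shifts.  The design is
#' factored once and reused across genes.  Constant mutation columns are
#' dropped with a warning; aliased (rank-deficient) columns are dropped and
#' recorded.
#'
#' Per-gene R-squared uses sequential sums of squares with confounders
#' entered first, so it isolates mutation-attributable variance:
#' `R2_g = (RSS_confounders - RSS_full) / SS_total`.
#'
#' @param expression genes x samples numeric matrix (log scale).
#' @param mutations samples x drivers binary matrix.
#' @param confounders optional `data.frame` of per-sample confounders (e.g.
#'   age, gender); factors are expanded to indicators.
#' @return Object of class `gene_fits`; see [moderate_statistics()] for the
#'   empirical-Bayes moderated statistics, [target_genes()] for
#'   mutation-centric gene sets, and the `coef`/`predict`/`summary` methods.
#' @export
fit_gene_models <- function(expression, mutations, confounders = NULL) {
  .check_binary_matrix(mutations)
  if (!identical(colnames(expression), rownames(mutations))) {
    stop("samples of expression (columns) and mutations (rows) differ",
         call. = FALSE)
  }
  n <- ncol(expression)
  mut <- mutations
  const <- apply(mut, 2, function(x) length(unique(x)) == 1)
  dropped_constant <- colnames(mut)[const]
  if (any(const)) {
    warning("dropping constant mutation column(s): ",
            paste(dropped_constant, collapse = ", "), call. = FALSE)
    mut <- mut[, !const, drop = FALSE]
  }
  conf <- .confounder_matrix(confounders, n)
  X <- cbind(`(Intercept)` = 1, mut, conf)
  p <- ncol(X)
  if (n < p + 2) stop("need at least (predictors + 2) samples", call. = FALSE)

  qr_x <- qr(X)
  dropped_aliased <- character(0)
  if (qr_x$rank < p) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped_aliased <- colnames(X)[setdiff(seq_len(p), keep)]
    warning("dropping aliased design column(s): ",
            paste(dropped_aliased, collapse = ", "), call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
    qr_x <- qr(X)
    p <- ncol(X)
  }
  mutation_cols <- setdiff(colnames(mut), dropped_aliased)
  confounder_cols <- setdiff(colnames(conf), dropped_aliased)

  Y <- t(expression)                               # samples x genes
  coefs <- qr.coef(qr_x, Y)                        # p x genes
  fitted <- qr.fitted(qr_x, Y)
  res <- Y - fitted
  rss <- colSums(res^2)
  d <- n - p
  sigma2 <- rss / d
  # reduced model: intercept + confounders only (sequential SS)
  X0 <- X[, c("(Intercept)", confounder_cols), drop = FALSE]
  rss0 <- colSums(qr.resid(qr(X0), Y)^2)
  ss_total <- colSums(scale(Y, scale = FALSE)^2)
  r2 <- (rss0 - rss) / ss_total
  r2[ss_total == 0] <- NA_real_
  r2 <- pmin(pmax(r2, 0), 1)

  xtx_inv <- chol2inv(qr.R(qr_x))
  stdev_unscaled <- sqrt(diag(xtx_inv))
  names(stdev_unscaled) <- colnames(X)

  structure(list(
    coefficients = t(coefs),                       # genes x p
    stdev_unscaled = stdev_unscaled,
    sigma2 = sigma2,
    df_residual = d,
    rss = rss,
    rss_reduced = rss0,
    ss_total = ss_total,
    r_squared = r2,
    mutation_cols = mutation_cols,
    confounder_cols = confounder_cols,
    dropped = list(constant = dropped_constant, aliased = dropped_aliased),
    n = n,
    design = X,
    genes = rownames(expression),
    moderated = NULL
  ), class = "gene_fits")
}

#' @export
print.gene_fits <- function(x, ...) {
  cat(sprintf("Per-gene additive mutation-expression fits: %d genes, %d samples\n",
              length(x$genes), x$n))
  cat(sprintf("  mutation terms: %d (%s, ...)\n", length(x$mutation_cols),
              paste(utils::head(x$mutation_cols, 4), collapse = ", ")))
  cat(sprintf("  confounders: %s\n",
              if (length(x$confounder_cols)) paste(x$confounder_cols,
                                                   collapse = ", ") else "none"))
  cat(sprintf("  residual df: %d\n", x$df_residual))
  if (!is.null(x$moderated)) {
    cat(sprintf("  moderated: prior df %.2f, prior variance %.3f\n",
                x$moderated$d0, x$moderated$s0_2))
  }
  invisible(x)
}

#' @export
coef.gene_fits <- function(object, ...) object$coefficients

#' @export
summary.gene_fits <- function(object, q_threshold = 0.01, ...) {
  out <- list(
    n_genes = length(object$genes),
    n_samples = object$n,
    r_squared = summary(object$r_squared)
  )
  if (!is.null(object$moderated)) {
    sig <- object$moderated$q < q_threshold
    out$n_significant <- sum(sig, na.rm = TRUE)
    out$min_r2_significant <- if (any(sig, na.rm = TRUE)) {
      min(object$r_squared[which(sig)], na.rm = TRUE)
    } else NA_real_
    out$q_threshold <- q_threshold
  }
  class(out) <- "summary.gene_fits"
  out
}

#' @export
print.summary.gene_fits <- function(x, ...) {
  cat(sprintf("%d genes, %d samples\n", x$n_genes, x$n_samples))
  cat("mutation-attributable R^2:\n")
  print(x$r_squared)
  if (!is.null(x$n_significant)) {
    cat(sprintf("genes with omnibus q < %g: %d (min R^2 among them: %.3f)\n",
                x$q_threshold, x$n_significant, x$min_r2_significant))
  }
  invisible(x)
}

#' Predict expression from genotype under the fitted additive model
#'
#' @param object a `gene_fits`.
#' @param mutations binary genotype matrix (samples x drivers) covering the
#'   fitted mutation columns.
#' @param confounders optional confounder `data.frame` matching the fit; if
#'   omitted, confounder terms contribute at zero (their indicator/centered
#'   value 0).
#' @param genes genes to predict (default all).
#' @param ... unused.
#' @return Matrix genes x samples of predicted log expression.
#' @export
predict.gene_fits <- function(object, mutations, confounders = NULL,
                              genes = NULL, ...) {
  genes <- genes %||% object$genes
  missing_genes <- setdiff(genes, object$genes)
  if (length(missing_genes)) {
    stop("unknown gene(s): ", paste(utils::head(missing_genes, 5),
                                    collapse = ", "), call. = FALSE)
  }
  n <- nrow(mutations)
  if (!all(object$mutation_cols %in% colnames(mutations))) {
    stop("genotype matrix lacks fitted mutation columns", call. = FALSE)
  }
  conf <- .confounder_matrix(confounders, n)
  X <- cbind(`(Intercept)` = rep(1, n),
             mutations[, object$mutation_cols, drop = FALSE])
  if (length(object$confounder_cols)) {
    cc <- matrix(0, n, length(object$confounder_cols),
                 dimnames = list(NULL, object$confounder_cols))
    shared <- intersect(colnames(conf), object$confounder_cols)
    cc[, shared] <- conf[, shared]
    X <- cbind(X, cc)
  }
  B <- object$coefficients[genes, colnames(X), drop = FALSE]
  out <- B %*% t(X)
  dimnames(out) <- list(genes, rownames(mutations))
  out
}

#' Predicted-versus-observed comparison for one gene
#'
#' Convenience wrapper around [predict.gene_fits()] reproducing the
#' per-gene scatter of model predictions against observed expression, with
#' their correlation.
#'
#' @param fits a `gene_fits`.
#' @param expression observed genes x samples matrix.
#' @param mutations genotype matrix used for prediction.
#' @param gene single gene identifier.
#' @param confounders optional confounders as in the fit.
#' @return `data.frame` with `sample`, `observed`, `predicted`; attributes
#'   `correlation` and `r_squared` (its square).
#' @export
predicted_vs_observed <- function(fits, expression, mutations, gene,
                                  confounders = NULL) {
  pred <- predict(fits, mutations, confounders, genes = gene)
  obs <- expression[gene, ]
  r <- stats::cor(drop(pred), obs)
  out <- data.frame(sample = colnames(expression), observed = obs,
                    predicted = drop(pred), stringsAsFactors = FALSE)
  attr(out, "correlation") <- r
  attr(out, "r_squared") <- r^2
  out
}

#' Per-gene mutation-attributable explained variance
#'
#' Returns the sequential R-squared of the mutation block (confounders
#' entered first) per gene, with a cohort-level distribution summary.
#'
#' @param fits a `gene_fits`.
#' @return `data.frame` with `gene`, `r_squared`; attribute `summary` holds
#'   the distribution summary.
#' @export
explained_variance <- function(fits) {
  stopifnot(inherits(fits, "gene_fits"))
  out <- data.frame(gene = fits$genes, r_squared = unname(fits$r_squared),
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- summary(fits$r_squared)
  out
}

#' Mutation-expression correlation matrix
#'
#' Pearson (point-biserial, since mutation status is binary) or Spearman
#' correlation between every driver mutation and every gene's expression.
#'
#' @param expression genes x samples matrix.
#' @param mutations samples x drivers binary matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @return drivers x genes correlation matrix in [-1, 1]; correlations
#'   involving a constant column are `NA`.
#' @export
mutation_expression_correlation <- function(expression, mutations,
                                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  .check_binary_matrix(mutations)
  if (ncol(expression) != nrow(mutations)) {
    stop("sample counts differ", call. = FALSE)
  }
  suppressWarnings(
    out <- t(stats::cor(t(expression), mutations, method = method))
  )
  out
}
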