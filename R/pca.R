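#' Principal-component decomposition of an expression matrix
#'
#' Gene-wise mean-centered PCA of a genes-by-samples log-expression matrix
#' via singular value decomposition, with full explained-variance
#' accounting.  By default genes are centered but not scaled to unit
#' variance: the decomposition reports variance fractions of the expression
#' data themselves, and scaling would equalize gene contributions.  Component
#' signs are fixed by convention — the largest-magnitude loading of each
#' component is made positive — so results are reproducible across runs and
#' platforms up to that convention.
#'
#' @param expression numeric matrix, genes x samples, no missing values.
#' @param n_components number of components to retain (>= 1).
#' @param scale. logical; also scale genes to unit variance before
#'   decomposition (default `FALSE`).
#' @return Object of class `expr_pca` with elements `scores`
#'   (samples x components, variance-carrying), `loadings`
#'   (genes x components, unit-norm columns), `explained_fraction`
#'   (retained components), `explained_fraction_all` (every component; sums
#'   to 1), `cumulative_fraction`, `centering_means`, `total_variance`,
#'   `n_components`, `scaled`.
#' @export
#' @examples
#' coh <- simulate_cohort(60, default_truth(n_genes = 100))
#' p <- fit_pca(coh$expression, 5)
#' p$explained_fraction
fit_pca <- function(expression, n_components, scale. = FALSE) {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    stop("'expression' must be a numeric matrix (genes x samples)",
         call. = FALSE)
  }
  if (anyNA(expression)) stop("expression contains missing values",
                              call. = FALSE)
  n <- ncol(expression); g <- nrow(expression)
  if (n < 2 || g < 2) stop("need at least 2 samples and 2 genes",
                           call. = FALSE)
  if (n_components < 1 || n_components > min(n, g)) {
    stop(sprintf("n_components must be in 1..%d", min(n, g)), call. = FALSE)
  }
  mu <- rowMeans(expression)
  x <- t(expression - mu)                      # samples x genes, centered
  sds <- NULL
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) stop("cannot scale zero-variance genes", call. = FALSE)
    x <- sweep(x, 2, sds, `/`)
  }
  sv <- svd(x)
  var_all <- sv$d^2 / (n - 1)
  expl_all <- var_all / sum(var_all)
  k <- n_components
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive (first on ties)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(colnames(expression), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(rownames(expression), paste0("PC", seq_len(k)))
  structure(list(
    scores = scores,
    loadings = loadings,
    explained_fraction = expl_all[seq_len(k)],
    explained_fraction_all = expl_all,
    cumulative_fraction = cumsum(expl_all)[seq_len(k)],
    centering_means = mu,
    scaling_sds = sds,
    total_variance = sum(var_all),
    n_components = k,
    scaled = scale.
  ), class = "expr_pca")
}

#' @export
print.expr_pca <- function(x, ...) {
  cat(sprintf("Expression PCA: %d components retained (of %d)\n",
              x$n_components, length(x$explained_fraction_all)))
  k <- min(5, x$n_components)
  cat(sprintf("  explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_len(k),
                            100 * x$explained_fraction[seq_len(k)]),
                    collapse = ", ")))
  cat(sprintf("  cumulative over retained: %.1f%%\n",
              100 * x$cumulative_fraction[x$n_components]))
  invisible(x)
}

#' @export
summary.expr_pca <- function(object, ...) {
  data.frame(
    component = paste0("PC", seq_len(object$n_components)),
    explained_fraction = object$explained_fraction,
    cumulative_fraction = object$cumulative_fraction
  )
}

#' @export
predict.expr_pca <- function(object, newdata, ...) {
  # project new genes-x-samples data onto the retained components
  x <- t(newdata - object$centering_means)
  if (object$scaled) x <- sweep(x, 2, object$scaling_sds, `/`)
  out <- x %*% object$loadings
  rownames(out) <- colnames(newdata)
  out
}

#' Top-loading genes of a principal component
#'
#' Ranks genes by absolute loading on one component, descending; ties are
#' broken lexicographically by gene identifier.
#'
#' @param pca an [fit_pca()] result.
#' @param component component index (retained).
#' @param k number of genes to return; `k = 0` gives an empty table, `k`
#'   beyond the gene count truncates with a warning.
#' @return `data.frame` with `gene`, `loading`, `rank`.
#' @export
top_loading_genes <- function(pca, component, k) {
  stopifnot(inherits(pca, "expr_pca"))
  if (component < 1 || component > pca$n_components) {
    stop("component not retained", call. = FALSE)
  }
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  l <- pca$loadings[, component]
  genes <- rownames(pca$loadings)
  if (k > length(l)) {
    warning(sprintf("k = %d exceeds gene count %d; truncating", k, length(l)),
            call. = FALSE)
    k <- length(l)
  }
  ord <- order(-abs(l), genes)
  idx <- utils::head(ord, k)
  data.frame(gene = genes[idx], loading = unname(l[idx]),
             rank = seq_len(length(idx)), stringsAsFactors = FALSE)
}

#' Per-sample overlay of PC scores, mutation status and demographics
#'
#' Builds the table behind the classic first-two-PCs scatter with mutation
#' status overlaid: one row per sample with PC1/PC2 scores, one logical
#' column per driver mutation, gender, and an age-above-cohort-median flag
#' (strictly greater than the median).
#'
#' @param pca an [fit_pca()] result (>= 2 retained components).
#' @param mutations binary samples x drivers matrix.
#' @param clinical clinical `data.frame` with `sample`, `age`, `gender`.
#' @return `data.frame`, one row per sample.
#' @export
overlay_table <- function(pca, mutations, clinical) {
  stopifnot(inherits(pca, "expr_pca"))
  if (pca$n_components < 2) stop("need at least two retained components",
                                 call. = FALSE)
  ids <- rownames(pca$scores)
  if (!identical(ids, rownames(mutations)) ||
      !identical(ids, clinical$sample)) {
    bad <- unique(c(setdiff(ids, rownames(mutations)),
                    setdiff(rownames(mutations), ids),
                    setdiff(ids, clinical$sample),
                    setdiff(clinical$sample, ids)))
    stop("sample identifiers mismatch between PCA, mutations and clinical",
         if (length(bad)) paste0(": ", paste(utils::head(bad, 10),
                                             collapse = ", ")) else
           " (ordering differs)",
         call. = FALSE)
  }
  med <- stats::median(clinical$age)
  out <- data.frame(sample = ids,
                    PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                    stringsAsFactors = FALSE)
  for (g in colnames(mutations)) out[[g]] <- mutations[, g] == 1
  out$gender <- clinical$gender
  out$age_above_median <- clinical$age > med
  attr(out, "age_median") <- med
  rownames(out) <- ids
  out
}
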