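# LASSO-penalized binomial phenotype models on mutations + expression PCs.

#' Build the standardized phenotype-model design matrix
#'
#' Concatenates the driver-mutation indicators with the first `n_pcs`
#' expression principal-component scores and standardizes every column to
#' zero mean and unit variance (constants stored for back-transformation).
#' Constant predictors are dropped with a warning.
#'
#' @param mutations binary samples x drivers matrix.
#' @param pca an [fit_pca()] result on the same samples.
#' @param n_pcs number of leading PCs to include (default 20; may be 0).
#' @return Standardized numeric matrix with attributes `center`, `scale`.
#' @export
build_design <- function(mutations, pca, n_pcs = 20) {
  stopifnot(inherits(pca, "expr_pca"))
  if (n_pcs > pca$n_components) {
    stop("n_pcs exceeds retained components", call. = FALSE)
  }
  if (!identical(rownames(mutations), rownames(pca$scores))) {
    stop("sample identifiers of mutations and PCA scores differ",
         call. = FALSE)
  }
  X <- cbind(mutations,
             pca$scores[, seq_len(n_pcs), drop = FALSE])
  const <- apply(X, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Xs <- scale(X, center = ctr, scale = scl)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- scl
  Xs
}

#' @noRd
.binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' @noRd
.stratified_folds <- function(y, folds, seed) {
  .with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  })
}

#' Cross-validated LASSO binomial model for one phenotype
#'
#' Fits the l1-penalized logistic regression of a binary phenotype on the
#' standardized design over a descending lambda grid, with stratified
#' k-fold cross-validation.  The CV metric is the deviance-based explained
#' variance \eqn{R^2(\lambda) = 1 - D_{cv}(\lambda)/D_{null}}, the fraction
#' of null binomial deviance explained on held-out samples; the optimal
#' lambda maximizes its CV mean.  Samples with missing phenotype are
#' excluded.  Predictor importance is recorded both as order of entry into
#' the path and as the rank of the absolute standardized coefficient at the
#' optimum; the "stable" flag marks predictors still active at the lambda
#' one standard error above the optimum.
#'
#' @param design standardized predictor matrix from [build_design()].
#' @param response binary phenotype (0/1, logical, or 2-level factor); `NA`
#'   entries are dropped with their rows.
#' @param folds number of CV folds (default 5); reduced with a warning when
#'   a class has fewer members than folds.
#' @param seed integer seed fixing the fold assignment.
#' @param phenotype optional label carried into the result.
#' @return Object of class `lasso_phen`.
#' @export
fit_lasso_cv <- function(design, response, folds = 5, seed = 1,
                         phenotype = NULL) {
  if (is.factor(response)) response <- as.integer(response) - 1L
  response <- as.numeric(response)
  keep <- !is.na(response)
  y <- response[keep]
  x <- design[keep, , drop = FALSE]
  if (!all(y %in% c(0, 1))) stop("response must be binary", call. = FALSE)
  n <- length(y)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (min(n_pos, n_neg) < 2) {
    stop("need at least 2 cases in each class", call. = FALSE)
  }
  if (min(n_pos, n_neg) < folds) {
    folds_new <- max(2L, min(n_pos, n_neg))
    warning(sprintf("reducing folds from %d to %d (smallest class has %d)",
                    folds, folds_new, min(n_pos, n_neg)), call. = FALSE)
    folds <- folds_new
  }

  full <- glmnet::glmnet(x, y, family = "binomial", standardize = FALSE)
  lambda <- full$lambda
  nl <- length(lambda)

  fold_id <- .stratified_folds(y, folds, .stream_seed(seed, "lasso_folds"))
  r2_fold <- matrix(NA_real_, folds, nl)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit_f <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                            family = "binomial", standardize = FALSE,
                            lambda = lambda)
    p_hat <- stats::predict(fit_f, x[!tr, , drop = FALSE],
                            type = "response")
    p0 <- mean(y[tr])
    dev_null <- .binomial_deviance(y[!tr], rep(p0, sum(!tr)))
    # the train path can terminate early; missing lambdas stay NA
    for (l in seq_len(ncol(p_hat))) {
      r2_fold[f, l] <- 1 - .binomial_deviance(y[!tr], p_hat[, l]) / dev_null
    }
  }
  ok <- colSums(is.na(r2_fold)) == 0
  r2_mean <- ifelse(ok, colMeans(r2_fold), -Inf)
  r2_sd <- apply(r2_fold, 2, stats::sd)
  i_opt <- which.max(r2_mean)          # ties -> first (largest lambda)
  se_opt <- r2_sd[i_opt] / sqrt(folds)
  i_1se <- which(r2_mean >= r2_mean[i_opt] - se_opt)[1]

  path <- as.matrix(full$beta)                     # p x nlambda, std scale
  coef_std <- path[, i_opt]
  ctr <- attr(design, "center"); scl <- attr(design, "scale")
  coef_raw <- coef_std / scl
  intercept_raw <- full$a0[i_opt] - sum(coef_std * ctr / scl)
  entry_order <- apply(path != 0, 1, function(nz) {
    if (any(nz)) which(nz)[1] else NA_integer_
  })
  rank_opt <- rep(NA_integer_, nrow(path))
  nz <- which(coef_std != 0)
  rank_opt[nz][order(-abs(coef_std[nz]))] <- seq_along(nz)
  names(rank_opt) <- rownames(path)
  stable_1se <- path[, i_1se] != 0

  lambda_max <- max(abs(crossprod(x, y - mean(y)))) / n

  structure(list(
    phenotype = phenotype %||% "phenotype",
    lambda = lambda,
    lambda_max = lambda_max,
    path = path,
    cv_r2_mean = ifelse(is.finite(r2_mean), r2_mean, NA_real_),
    cv_r2_sd = r2_sd,
    cv_r2_fold = r2_fold,
    lambda_opt = lambda[i_opt],
    lambda_1se = lambda[i_1se],
    cv_r2_opt = r2_mean[i_opt],
    coef_std = coef_std,
    coef_raw = coef_raw,
    intercept_raw = intercept_raw,
    entry_order = entry_order,
    importance_rank = rank_opt,
    stable_1se = stable_1se,
    folds = folds,
    fold_id = fold_id,
    seed = seed,
    n = n,
    n_cases = n_pos,
    glmnet_fit = full
  ), class = "lasso_phen")
}

#' @export
print.lasso_phen <- function(x, ...) {
  cat(sprintf("LASSO binomial phenotype model: %s\n", x$phenotype))
  cat(sprintf("  n = %d (%d cases), %d-fold stratified CV\n",
              x$n, x$n_cases, x$folds))
  cat(sprintf("  optimal lambda %.4g; CV explained deviance R^2 = %.3f\n",
              x$lambda_opt, x$cv_r2_opt))
  nz <- which(x$coef_std != 0)
  cat(sprintf("  nonzero predictors at optimum: %d\n", length(nz)))
  if (length(nz)) {
    top <- utils::head(nz[order(-abs(x$coef_std[nz]))], 5)
    cat(sprintf("  top: %s\n",
                paste(sprintf("%s (%.3f)", names(x$coef_std)[top],
                              x$coef_std[top]), collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.lasso_phen <- function(object, lambda = NULL,
                            scale = c("standardized", "original"), ...) {
  scale <- match.arg(scale)
  if (is.null(lambda)) {
    if (scale == "standardized") return(object$coef_std)
    return(c(`(Intercept)` = object$intercept_raw, object$coef_raw))
  }
  b <- drop(as.matrix(stats::predict(object$glmnet_fit, s = lambda,
                                     type = "coefficients",
                                     exact = FALSE)))
  if (scale == "standardized") return(b[-1])
  b
}

#' @export
plot.lasso_phen <- function(x, ...) {
  graphics::plot(log(x$lambda), x$cv_r2_mean, type = "l", col = "red",
                 xlab = expression(log(lambda)),
                 ylab = expression(paste("CV explained variance ", R^2)),
                 main = x$phenotype, ...)
  up <- x$cv_r2_mean + x$cv_r2_sd
  dn <- x$cv_r2_mean - x$cv_r2_sd
  graphics::lines(log(x$lambda), up, lty = 3)
  graphics::lines(log(x$lambda), dn, lty = 3)
  graphics::abline(v = log(x$lambda_opt), lty = 2)
  invisible(x)
}

#' Cross-phenotype coefficient importance table
#'
#' Combines a collection of [fit_lasso_cv()] results into a
#' phenotype-by-predictor table of optimal-model coefficients on the common
#' standardized scale, with the within-phenotype importance rank of each
#' nonzero coefficient and a stability flag (nonzero at the lambda one
#' standard error above the optimum).
#'
#' @param results named list of `lasso_phen` objects (>= 1).
#' @return Object of class `lasso_importance`: list with `coefficients`
#'   (phenotype x predictor matrix), `rank` (same shape, NA where zero),
#'   `stable` (logical matrix), and `all_zero` (phenotypes whose optimal
#'   model is empty).
#' @export
importance_heatmap <- function(results) {
  if (!length(results)) stop("need at least one result", call. = FALSE)
  if (is.null(names(results))) {
    names(results) <- vapply(results, function(r) r$phenotype, "")
  }
  preds <- unique(unlist(lapply(results, function(r) names(r$coef_std))))
  mk <- function(fill) matrix(fill, length(results), length(preds),
                              dimnames = list(names(results), preds))
  co <- mk(0); rk <- mk(NA_integer_); st <- mk(FALSE)
  for (ph in names(results)) {
    r <- results[[ph]]
    co[ph, names(r$coef_std)] <- r$coef_std
    rk[ph, names(r$importance_rank)] <- r$importance_rank
    st[ph, names(r$stable_1se)] <- r$stable_1se
  }
  structure(list(coefficients = co, rank = rk, stable = st,
                 all_zero = rownames(co)[rowSums(co != 0) == 0]),
            class = "lasso_importance")
}

#' @export
print.lasso_importance <- function(x, ...) {
  cat(sprintf("LASSO importance table: %d phenotypes x %d predictors\n",
              nrow(x$coefficients), ncol(x$coefficients)))
  if (length(x$all_zero)) {
    cat("  all-zero optimal models: ", paste(x$all_zero, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Binary phenotype indicators from a clinical table
#'
#' Expands the clinical table into the named binary responses modelled by
#' the phenotype stage: one indicator per histologic subtype (NA where
#' subtype is unobserved), one per pathological stage, plus
#' age-above-median, gender (female), and smoking history.
#'
#' @param clinical clinical `data.frame` with `subtype`, `stage`, `age`,
#'   `gender`, `smoking`.
#' @return Named list of numeric 0/1 vectors (with NA for missing).
#' @export
phenotype_indicators <- function(clinical) {
  out <- list()
  if (!is.null(clinical$subtype)) {
    for (s in sort(unique(stats::na.omit(clinical$subtype)))) {
      out[[paste0("subtype_", s)]] <-
        ifelse(is.na(clinical$subtype), NA, as.numeric(clinical$subtype == s))
    }
  }
  for (s in sort(unique(clinical$stage))) {
    out[[paste0("stage_", s)]] <- as.numeric(clinical$stage == s)
  }
  out$age_above_median <- as.numeric(clinical$age > stats::median(clinical$age))
  out$female <- as.numeric(clinical$gender == "female")
  out$smoker <- as.numeric(clinical$smoking == "smoker")
  out
}
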