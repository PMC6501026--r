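# Block-structured Cox proportional-hazards modelling, cross-validated
# Harrell's C, model comparison, and per-block risk decomposition.

#' Assemble the five survival covariate blocks from cohort components
#'
#' Builds the named block design used by the survival stage: `genetics`
#' (driver-mutation indicators), `expression` (leading principal-component
#' scores — the transcriptome enters through PCs, not through thousands of
#' individual genes), `pathology` (histologic-subtype indicators, first
#' level as reference),
#' `demographics` (standardized age, gender, smoking) and `stage`
#' (pathological-stage indicators, stage I as reference).
#'
#' Samples with unobserved subtype are handled by default with a
#' missing-category indicator (all subtype indicators zero plus an
#' explicit `missing` column), so no sample is lost; `missing_subtype =
#' "complete"` instead restricts every block to samples with observed
#' subtype.
#'
#' @param mutations binary samples x drivers matrix.
#' @param pca an [fit_pca()] result on the same samples (or `NULL` to omit
#'   the expression block).
#' @param clinical clinical `data.frame`.
#' @param n_pcs number of PC scores in the expression block.
#' @param blocks which blocks to build.
#' @param missing_subtype `"indicator"` (default) or `"complete"`.
#' @return Named list of numeric matrices with identical row names;
#'   attribute `samples` records the retained sample identifiers.
#' @export
survival_blocks <- function(mutations, pca = NULL, clinical, n_pcs = 20,
                            blocks = c("genetics", "expression", "pathology",
                                       "demographics", "stage"),
                            missing_subtype = c("indicator", "complete")) {
  missing_subtype <- match.arg(missing_subtype)
  ids <- clinical$sample
  keep <- rep(TRUE, length(ids))
  if (missing_subtype == "complete" && "pathology" %in% blocks) {
    keep <- !is.na(clinical$subtype)
  }
  out <- list()
  if ("genetics" %in% blocks) {
    stopifnot(identical(rownames(mutations), ids))
    out$genetics <- mutations[keep, , drop = FALSE]
  }
  if ("expression" %in% blocks && !is.null(pca) && n_pcs > 0) {
    stopifnot(identical(rownames(pca$scores), ids))
    out$expression <- pca$scores[keep, seq_len(n_pcs), drop = FALSE]
  }
  if ("pathology" %in% blocks) {
    lv <- sort(unique(stats::na.omit(clinical$subtype)))
    # first level is the reference: indicator sets summing to a constant
    # are unidentifiable in the partial likelihood
    if (length(lv) > 1) lv <- lv[-1]
    sub <- clinical$subtype[keep]
    M <- sapply(lv, function(l) as.numeric(!is.na(sub) & sub == l))
    if (missing_subtype == "indicator") {
      M <- cbind(M, missing = as.numeric(is.na(sub)))
    }
    if (is.null(dim(M))) M <- matrix(M, nrow = sum(keep))
    rownames(M) <- ids[keep]
    out$pathology <- M
  }
  if ("demographics" %in% blocks) {
    demo <- cbind(
      age = as.numeric(scale(clinical$age))[keep],
      male = as.numeric(clinical$gender == "male")[keep],
      smoker = as.numeric(clinical$smoking == "smoker")[keep]
    )
    rownames(demo) <- ids[keep]
    out$demographics <- demo
  }
  if ("stage" %in% blocks) {
    st <- clinical$stage[keep]
    M <- sapply(c("II", "III", "IV"), function(l) as.numeric(st == l))
    if (is.null(dim(M))) M <- matrix(M, nrow = sum(keep),
                                     dimnames = list(NULL, c("II", "III", "IV")))
    rownames(M) <- ids[keep]
    out$stage <- M
  }
  attr(out, "samples") <- ids[keep]
  out
}

#' @noRd
.bind_blocks <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1, !is.null(names(blocks)))
  X <- do.call(cbind, lapply(names(blocks), function(b) {
    M <- as.matrix(blocks[[b]])
    colnames(M) <- paste(b, colnames(M) %||% seq_len(ncol(M)), sep = ".")
    M
  }))
  map <- rep(names(blocks), vapply(blocks, ncol, 1L))
  names(map) <- colnames(X)
  list(X = X, map = map)
}

#' Fit a block-structured Cox proportional-hazards model
#'
#' Fits the Cox model on the concatenated covariate blocks (Efron tie
#' handling by default, Breslow available; optional ridge stabilizer) and
#' records, for every sample, the per-block components of the linear
#' predictor, which sum to the linear predictor exactly — the basis of the
#' risk decomposition.
#'
#' @param blocks named list of numeric matrices (same rows, e.g. from
#'   [survival_blocks()]).
#' @param time,event right-censored outcome (time >= 0, event 0/1).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param ridge optional ridge penalty (default 0 = none), recorded in the
#'   output.
#' @return Object of class `cox_block_fit` with `coefficients`,
#'   `block_map`, `loglik`, `lp`, `components` (samples x blocks),
#'   `convergence` diagnostics and the underlying `survival::coxph` fit.
#' @export
fit_cox_blocks <- function(blocks, time, event, ties = c("efron", "breslow"),
                           ridge = 0) {
  ties <- match.arg(ties)
  bb <- .bind_blocks(blocks)
  X <- bb$X
  n <- nrow(X)
  stopifnot(length(time) == n, length(event) == n)
  if (any(time < 0)) stop("negative survival times", call. = FALSE)
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  if (anyNA(X)) stop("missing covariate values; encode or drop them first",
                     call. = FALSE)
  df <- data.frame(X, check.names = FALSE)
  df$.time <- time
  df$.event <- event
  vars <- sprintf("`%s`", colnames(X))
  rhs <- if (ridge > 0) {
    sprintf("ridge(%s, theta = %g, scale = TRUE)",
            paste(vars, collapse = ", "), ridge)
  } else paste(vars, collapse = " + ")
  f <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- survival::coxph(f, data = df, ties = ties)
  beta <- stats::coef(fit)
  # coxph names ridge() coefficients with a prefix; restore design names
  if (length(beta) == ncol(X)) names(beta) <- colnames(X)
  aliased <- is.na(beta)
  if (any(aliased)) {
    warning("aliased coefficient(s) set to zero: ",
            paste(names(beta)[aliased], collapse = ", "), call. = FALSE)
    beta[aliased] <- 0
  }
  comp <- sapply(unique(bb$map), function(b) {
    cols <- names(bb$map)[bb$map == b]
    drop(X[, cols, drop = FALSE] %*% beta[cols])
  })
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = n,
                                         dimnames = list(NULL, unique(bb$map)))
  rownames(comp) <- rownames(X)
  lp <- rowSums(comp)
  structure(list(
    coefficients = beta,
    block_map = bb$map,
    loglik = fit$loglik,
    lp = lp,
    components = comp,
    time = time,
    event = event,
    ties = ties,
    ridge = ridge,
    convergence = list(iter = fit$iter,
                       score_norm = tryCatch(
                         max(abs(colSums(as.matrix(
                           survival::coxph.detail(fit)$score)))),
                         error = function(e) NA_real_)),
    coxph = fit
  ), class = "cox_block_fit")
}

#' @export
print.cox_block_fit <- function(x, ...) {
  cat("Block-structured Cox proportional-hazards fit\n")
  cat(sprintf("  n = %d, events = %d; ties = %s%s\n", length(x$lp),
              sum(x$event), x$ties,
              if (x$ridge > 0) sprintf(", ridge = %g", x$ridge) else ""))
  cat(sprintf("  blocks: %s\n",
              paste(sprintf("%s (%d)", unique(x$block_map),
                            table(factor(x$block_map,
                                         levels = unique(x$block_map)))),
                    collapse = ", ")))
  cat(sprintf("  partial log-likelihood: %.2f -> %.2f\n",
              x$loglik[1], x$loglik[2]))
  invisible(x)
}

#' @export
coef.cox_block_fit <- function(object, ...) object$coefficients

#' @export
predict.cox_block_fit <- function(object, newblocks, type = c("lp", "components"),
                                  ...) {
  type <- match.arg(type)
  bb <- .bind_blocks(newblocks)
  if (!identical(colnames(bb$X), names(object$coefficients))) {
    stop("new blocks do not match the fitted design", call. = FALSE)
  }
  comp <- sapply(unique(bb$map), function(b) {
    cols <- names(bb$map)[bb$map == b]
    drop(bb$X[, cols, drop = FALSE] %*% object$coefficients[cols])
  })
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = nrow(bb$X),
                                         dimnames = list(NULL, unique(bb$map)))
  rownames(comp) <- rownames(bb$X)
  if (type == "components") return(comp)
  rowSums(comp)
}

#' @export
summary.cox_block_fit <- function(object, ...) {
  summary(object$coxph, ...)
}

#' Harrell's concordance index under right censoring
#'
#' The probability, over all comparable sample pairs, that the sample with
#' the higher predicted risk fails first.  A pair is comparable when the
#' earlier time is an observed event (including an event tied in time with
#' a censored observation); tied risks count one half.  C = 0.5 is chance
#' level, C = 1 a perfect ranking.
#'
#' @param risk numeric per-sample risk score (higher = worse prognosis).
#' @param time,event right-censored outcome.
#' @return Object of class `concordance_estimate`: list with
#'   `concordance` (fraction), `percent`, `comparable`, `concordant`,
#'   `discordant`, `tied_risk`.
#' @export
#' @examples
#' # perfect ranking: risk reverses time order
#' harrell_c(-(1:10), 1:10, rep(1, 10))$percent
harrell_c <- function(risk, time, event) {
  n <- length(time)
  stopifnot(length(risk) == n, length(event) == n,
            all(event %in% c(0, 1)))
  conc <- disc <- tied <- 0
  for (i in which(event == 1)) {
    cmp <- (time > time[i]) | (time == time[i] & event == 0)
    cmp[i] <- FALSE
    if (!any(cmp)) next
    d <- risk[i] - risk[cmp]
    conc <- conc + sum(d > 0)
    disc <- disc + sum(d < 0)
    tied <- tied + sum(d == 0)
  }
  total <- conc + disc + tied
  if (total == 0) stop("no comparable pairs under censoring", call. = FALSE)
  cidx <- (conc + 0.5 * tied) / total
  structure(list(concordance = cidx, percent = 100 * cidx,
                 comparable = total, concordant = conc,
                 discordant = disc, tied_risk = tied),
            class = "concordance_estimate")
}

#' @export
print.concordance_estimate <- function(x, ...) {
  cat(sprintf("Harrell's C = %.1f%% (%d comparable pairs)\n",
              x$percent, x$comparable))
  invisible(x)
}

#' @noRd
.survival_folds <- function(event, folds, seed, min_events = 2) {
  # event-stratified partition; every fold carries events
  for (try in 0:20) {
    f <- .stratified_folds(event, folds, .stream_seed(seed, paste0("cvfold", try)))
    ev_per <- tapply(event, f, sum)
    if (all(ev_per >= min_events)) {
      if (try > 0) warning("refolded to avoid event-free fold", call. = FALSE)
      return(f)
    }
  }
  stop("could not build folds with >= 2 events each", call. = FALSE)
}

#' Cross-validated concordance of a block Cox model
#'
#' Five-fold scheme in which, by default, each quintile of the data in turn
#' is used to train the model and Harrell's C is evaluated on the four
#' quintiles set aside, the average across the five quintiles being the
#' conclusive estimate (`scheme = "quintile-train"`).  The conventional
#' scheme (train on four fifths, test on one) is available as
#' `scheme = "conventional"`.  Folds are stratified by event status and
#' fixed by `seed`.
#'
#' @param blocks named list of covariate matrices.
#' @param time,event right-censored outcome.
#' @param folds number of folds (default 5).
#' @param seed integer seed fixing fold assignment.
#' @param scheme `"quintile-train"` (default) or `"conventional"`.
#' @param ties,ridge passed to [fit_cox_blocks()].
#' @return Object of class `concordance_report`: `per_fold` C values,
#'   `mean`, `sd`, `fold_id`, `scheme`.
#' @export
cv_concordance <- function(blocks, time, event, folds = 5, seed = 1,
                           scheme = c("quintile-train", "conventional"),
                           ties = "efron", ridge = 0) {
  scheme <- match.arg(scheme)
  fold_id <- .survival_folds(event, folds, seed)
  cs <- vapply(seq_len(folds), function(f) {
    tr <- if (scheme == "quintile-train") fold_id == f else fold_id != f
    fit <- fit_cox_blocks(lapply(blocks, function(M) M[tr, , drop = FALSE]),
                          time[tr], event[tr], ties = ties, ridge = ridge)
    lp_test <- predict(fit, lapply(blocks, function(M) M[!tr, , drop = FALSE]))
    harrell_c(lp_test, time[!tr], event[!tr])$concordance
  }, 0)
  structure(list(per_fold = cs, mean = mean(cs), sd = stats::sd(cs),
                 fold_id = fold_id, folds = folds, seed = seed,
                 scheme = scheme),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Cross-validated Harrell's C (%d folds, %s scheme)\n",
              x$folds, x$scheme))
  cat(sprintf("  mean C = %.1f%% (sd %.1f); per fold: %s\n",
              100 * x$mean, 100 * x$sd,
              paste(sprintf("%.1f%%", 100 * x$per_fold), collapse = ", ")))
  invisible(x)
}

#' Paired cross-validated comparison of two block Cox models
#'
#' Repeats cross-validated concordance estimation for a full and a reduced
#' model specification on identical folds, and tests the paired per-fold C
#' differences with a sign-flip permutation test (two-sided).
#'
#' @param blocks_full,blocks_reduced named lists of covariate matrices on
#'   the same samples.
#' @param time,event right-censored outcome.
#' @param folds folds per repeat.
#' @param seed master seed; each repeat derives its fold seed from it.
#' @param n_repeats number of cross-validation repeats.
#' @param n_perm sign-flip permutations for the p-value.
#' @param scheme CV scheme as in [cv_concordance()].
#' @return Object of class `model_comparison`: per-fold C for both models,
#'   mean difference, permutation `p_value`, and `direction`.
#' @export
compare_models <- function(blocks_full, blocks_reduced, time, event,
                           folds = 5, seed = 1, n_repeats = 10,
                           n_perm = 10000,
                           scheme = c("quintile-train", "conventional")) {
  scheme <- match.arg(scheme)
  n_full <- nrow(blocks_full[[1]]); n_red <- nrow(blocks_reduced[[1]])
  if (n_full != n_red) stop("models must share samples", call. = FALSE)
  c_full <- c_red <- numeric(0)
  for (r in seq_len(n_repeats)) {
    s <- .stream_seed(seed, paste0("compare", r))
    fold_id <- .survival_folds(event, folds, s)
    for (f in seq_len(folds)) {
      tr <- if (scheme == "quintile-train") fold_id == f else fold_id != f
      eval_one <- function(blocks) {
        fit <- fit_cox_blocks(lapply(blocks, function(M) M[tr, , drop = FALSE]),
                              time[tr], event[tr])
        lp <- predict(fit, lapply(blocks, function(M) M[!tr, , drop = FALSE]))
        harrell_c(lp, time[!tr], event[!tr])$concordance
      }
      c_full <- c(c_full, eval_one(blocks_full))
      c_red <- c(c_red, eval_one(blocks_reduced))
    }
  }
  d <- c_full - c_red
  obs <- mean(d)
  flips <- .with_seed(.stream_seed(seed, "signflip"), {
    matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
           n_perm, length(d))
  })
  null_means <- drop(flips %*% d) / length(d)
  p <- (1 + sum(abs(null_means) >= abs(obs))) / (n_perm + 1)
  structure(list(
    c_full = c_full, c_reduced = c_red,
    mean_full = mean(c_full), mean_reduced = mean(c_red),
    difference = obs, p_value = p,
    direction = if (obs > 0) "full > reduced" else if (obs < 0)
      "full < reduced" else "equal",
    folds = folds, n_repeats = n_repeats, scheme = scheme, seed = seed
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Paired CV comparison (%d repeats x %d folds, %s scheme)\n",
              x$n_repeats, x$folds, x$scheme))
  cat(sprintf("  C full = %.1f%%, C reduced = %.1f%%, difference = %+.1f points\n",
              100 * x$mean_full, 100 * x$mean_reduced, 100 * x$difference))
  cat(sprintf("  sign-flip permutation p = %.4g (%s)\n", x$p_value,
              x$direction))
  invisible(x)
}

#' Per-block risk-contribution decomposition
#'
#' Attributes the variability of the linear predictor to the covariate
#' blocks: the contribution of block b is the variance of its component of
#' the linear predictor, with the covariance between any two blocks
#' allocated half to each — equivalently
#' \eqn{f_b = cov(c_b, lp)/var(lp)}, so the fractions sum to one exactly.
#' A marginal-drop alternative (the change in Harrell's C when block b is
#' removed from the risk score) is emitted alongside.
#'
#' @param fit a [fit_cox_blocks()] result.
#' @param components optional samples x blocks component matrix (defaults
#'   to the fitted one; supply `predict(fit, newblocks, "components")` for
#'   new data).
#' @param time,event outcome for the marginal-drop column (defaults to the
#'   fitted outcome; `NULL` skips it).
#' @return Object of class `risk_decomposition`: `data.frame` with
#'   `block`, `fraction`, `delta_c`.
#' @export
risk_contributions <- function(fit, components = NULL, time = fit$time,
                               event = fit$event) {
  stopifnot(inherits(fit, "cox_block_fit"))
  comp <- components %||% fit$components
  lp <- rowSums(comp)
  v <- stats::var(lp)
  if (v == 0) stop("zero-variance linear predictor: contributions undefined",
                   call. = FALSE)
  frac <- apply(comp, 2, function(cb) stats::cov(cb, lp)) / v
  dc <- rep(NA_real_, ncol(comp))
  if (!is.null(time) && !is.null(event)) {
    c_all <- harrell_c(lp, time, event)$concordance
    dc <- vapply(seq_len(ncol(comp)), function(b) {
      c_all - harrell_c(lp - comp[, b], time, event)$concordance
    }, 0)
  }
  structure(data.frame(block = colnames(comp), fraction = unname(frac),
                       delta_c = unname(dc), stringsAsFactors = FALSE),
            class = c("risk_decomposition", "data.frame"))
}

#' @export
print.risk_decomposition <- function(x, ...) {
  cat("Risk-contribution decomposition\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-14s %5.1f%%%s\n", x$block[i], 100 * x$fraction[i],
                if (!is.na(x$delta_c[i]))
                  sprintf("  (marginal-drop dC = %+.3f)", x$delta_c[i]) else ""))
  }
  invisible(x)
}

#' Kaplan-Meier estimates per group with a log-rank test
#'
#' Product-limit survival estimates (Greenwood standard errors) for a
#' sample partition, with the log-rank test across groups.  Empty or
#' missing groups are dropped with a warning.
#'
#' @param groups per-sample group labels.
#' @param time,event right-censored outcome.
#' @return Object of class `km_fit`: `curves` (long `data.frame`: `group`,
#'   `time`, `n_risk`, `n_event`, `surv`, `std_err`, `lower`, `upper`),
#'   `logrank_chisq`, `logrank_df`, `logrank_p`, and the underlying
#'   `survfit` object.
#' @export
km_estimate <- function(groups, time, event) {
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  keep <- !is.na(groups)
  if (any(!keep)) {
    warning(sprintf("dropping %d sample(s) with missing group", sum(!keep)),
            call. = FALSE)
  }
  g <- factor(groups[keep])
  g <- droplevels(g)
  time <- time[keep]; event <- event[keep]
  df <- data.frame(time = time, event = event, group = g)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                          conf.type = "log")
  ss <- summary(sf, censored = FALSE)
  grp <- if (is.null(ss$strata)) rep(levels(g)[1], length(ss$time)) else {
    sub("^group=", "", as.character(ss$strata))
  }
  curves <- data.frame(group = grp, time = ss$time, n_risk = ss$n.risk,
                       n_event = ss$n.event, surv = ss$surv,
                       std_err = ss$std.err, lower = ss$lower,
                       upper = ss$upper, stringsAsFactors = FALSE)
  lr <- list(chisq = NA_real_, df = NA_integer_, p = NA_real_)
  if (nlevels(g) >= 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    df_lr <- length(sd$n) - 1
    lr <- list(chisq = sd$chisq, df = df_lr,
               p = stats::pchisq(sd$chisq, df_lr, lower.tail = FALSE))
  }
  structure(list(curves = curves, logrank_chisq = lr$chisq,
                 logrank_df = lr$df, logrank_p = lr$p, survfit = sf),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimates: %d group(s)\n",
              length(unique(x$curves$group))))
  if (!is.na(x$logrank_p)) {
    cat(sprintf("  log-rank chi-square = %.2f on %d df, p = %.4g\n",
                x$logrank_chisq, x$logrank_df, x$logrank_p))
  }
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ...) {
  plot(x$survfit, xlab = "time", ylab = "survival probability", ...)
  invisible(x)
}
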