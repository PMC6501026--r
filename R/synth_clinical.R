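# Clinical covariates and Weibull proportional-hazards survival generation.

#' @noRd
.calibrate_censoring <- function(times, target, u, tol = 0.002, maxit = 200) {
  # Exponential censoring times C = -log(u)/rate; find rate so that the
  # realized censored fraction mean(C < T) hits `target`.  Monotone in rate,
  # solved by bisection on log-rate.
  f <- function(lr) mean(-log(u) / exp(lr) < times) - target
  lo <- log(1e-8); hi <- log(1e8)
  if (f(lo) > target + tol || f(hi) < -tol) {
    # (f(lo) ~ -target at tiny rates; unreachable only in degenerate cases)
  }
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  rate <- exp((lo + hi) / 2)
  cens <- -log(u) / rate
  realized <- mean(cens < times)
  if (abs(realized - target) > max(tol, 2 / length(times))) {
    warning(sprintf(
      "target censoring rate %.3f unreachable; realized %.3f", target,
      realized), call. = FALSE)
  }
  list(rate = rate, cens = cens, realized = realized)
}

#' @noRd
.stage_features <- function(stage) {
  lv <- c("I", "II", "III", "IV")
  out <- sapply(lv, function(l) as.numeric(stage == l))
  colnames(out) <- lv
  out
}

#' @noRd
.subtype_features <- function(subtype, levels) {
  out <- sapply(levels, function(l) as.numeric(subtype == l))
  colnames(out) <- levels
  out
}

#' Generate clinical covariates and censored survival outcomes
#'
#' Draws age, gender, smoking history, pathological stage and histologic
#' subtype from the configured categorical distributions (subtype optionally
#' tilted by genotype through `truth$subtype_link`), forms the true
#' log-hazard as the sum of the per-block contributions
#' `genetics + expression + pathology + demographics + stage`, and draws two
#' correlated right-censored event-time channels (overall survival and
#' recurrence-free survival) from a Weibull proportional-hazards model with
#' a shared log-normal frailty.  Censoring is independent exponential with
#' rate calibrated by bisection to the target `truth$censor_rate`; the
#' realized fraction is recorded.
#'
#' The expression block of the log-hazard uses the realized latent factor
#' scores carried by [generate_expression()] (attribute `latent_scores`),
#' i.e. the true low-dimensional expression state, not the noisy gene-level
#' measurements.
#'
#' @param mutations binary mutation matrix (samples x drivers).
#' @param expression expression matrix from [generate_expression()].
#' @param truth a [sim_truth()] object.
#' @return A `data.frame` with one row per sample: `sample`, `age`,
#'   `gender`, `smoking`, `stage`, `subtype` (NA where masked as
#'   unobserved), `os_time`, `os_event`, `rfs_time`, `rfs_event`.
#'   Attributes: `true_lp` (per-sample log-hazard), `block_components`
#'   (samples x blocks matrix summing to `true_lp`), `subtype_full`
#'   (pre-masking subtype), `realized_censoring` (named, OS and RFS).
#' @export
generate_clinical_and_survival <- function(mutations, expression, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  .check_binary_matrix(mutations)
  if (!identical(rownames(mutations), colnames(expression))) {
    stop("sample identifiers of mutations and expression differ",
         call. = FALSE)
  }
  n <- nrow(mutations)
  ids <- rownames(mutations)
  z <- attr(expression, "latent_scores")
  if (is.null(z) && truth$n_latent > 0 &&
      any(truth$block_betas$expression %||% 0 != 0)) {
    stop("expression matrix lacks the 'latent_scores' attribute needed for ",
         "the expression block of the log-hazard", call. = FALSE)
  }

  subtype_levels <- names(truth$subtype_probs)
  .with_seed(.stream_seed(truth$seed, "clinical"), {
    age <- round(stats::rnorm(n, truth$age_mean, truth$age_sd))
    age <- pmin(pmax(age, truth$age_range[1]), truth$age_range[2])
    gender <- ifelse(stats::runif(n) < truth$female_prob, "female", "male")
    smoking <- ifelse(stats::runif(n) < truth$smoker_prob,
                      "smoker", "non-smoker")
    stage <- sample(names(truth$stage_probs), n, replace = TRUE,
                    prob = truth$stage_probs)
    # subtype: multinomial with optional genotype-dependent logit tilt
    base_lo <- log(truth$subtype_probs)
    lo <- matrix(base_lo, n, length(subtype_levels), byrow = TRUE)
    if (!is.null(truth$subtype_link)) {
      for (k in seq_along(subtype_levels)) {
        b <- truth$subtype_link[[subtype_levels[k]]]
        if (!is.null(b)) lo[, k] <- lo[, k] + drop(mutations %*% b)
      }
    }
    pr <- exp(lo - apply(lo, 1, max))
    pr <- pr / rowSums(pr)
    gmb <- matrix(-log(-log(stats::runif(n * ncol(pr)))), n, ncol(pr))
    subtype_full <- subtype_levels[max.col(log(pr) + gmb)]
    observed <- stats::runif(n) < truth$subtype_obs_rate
    u_os <- stats::runif(n)
    u_rfs <- stats::runif(n)
    frailty <- stats::rnorm(n, 0, truth$frailty_sd)
    u_cens_os <- stats::runif(n)
    u_cens_rfs <- stats::runif(n)
  })

  bb <- truth$block_betas
  comp <- matrix(0, n, 5,
                 dimnames = list(ids, c("genetics", "expression", "pathology",
                                        "demographics", "stage")))
  if (!is.null(bb$genetics)) {
    comp[, "genetics"] <- drop(mutations %*% bb$genetics)
  }
  if (!is.null(bb$expression) && truth$n_latent > 0 &&
      length(bb$expression) > 0) {
    comp[, "expression"] <- drop(z %*% bb$expression)
  }
  if (!is.null(bb$pathology)) {
    comp[, "pathology"] <- drop(.subtype_features(subtype_full,
                                                  subtype_levels) %*%
                                  bb$pathology[subtype_levels])
  }
  if (!is.null(bb$demographics)) {
    demo <- cbind(age = (age - truth$age_mean) / truth$age_sd,
                  male = as.numeric(gender == "male"),
                  smoker = as.numeric(smoking == "smoker"))
    comp[, "demographics"] <- drop(demo %*% bb$demographics)
  }
  if (!is.null(bb$stage)) {
    comp[, "stage"] <- drop(.stage_features(stage) %*%
                              bb$stage[c("I", "II", "III", "IV")])
  }
  lp <- rowSums(comp)

  # Weibull PH: S(t|lp) = exp(-(t/scale)^shape * exp(lp))
  draw_times <- function(u, lin) {
    truth$baseline_scale * (-log(u) / exp(lin))^(1 / truth$baseline_shape)
  }
  t_os <- draw_times(u_os, lp + frailty)
  t_rfs <- draw_times(u_rfs, truth$rfs_scale * lp + frailty)

  realized <- c(os = 0, rfs = 0)
  if (truth$censor_rate == 0) {
    os_time <- t_os; os_event <- rep(1L, n)
    rfs_time <- t_rfs; rfs_event <- rep(1L, n)
  } else {
    cal_os <- .calibrate_censoring(t_os, truth$censor_rate, u_cens_os)
    cal_rfs <- .calibrate_censoring(t_rfs, truth$censor_rate, u_cens_rfs)
    os_event <- as.integer(t_os <= cal_os$cens)
    os_time <- pmin(t_os, cal_os$cens)
    rfs_event <- as.integer(t_rfs <= cal_rfs$cens)
    rfs_time <- pmin(t_rfs, cal_rfs$cens)
    realized <- c(os = cal_os$realized, rfs = cal_rfs$realized)
  }

  clin <- data.frame(
    sample = ids, age = age, gender = gender, smoking = smoking,
    stage = stage,
    subtype = ifelse(observed, subtype_full, NA_character_),
    os_time = os_time, os_event = os_event,
    rfs_time = rfs_time, rfs_event = rfs_event,
    stringsAsFactors = FALSE
  )
  rownames(clin) <- ids
  attr(clin, "true_lp") <- lp
  attr(clin, "block_components") <- comp
  attr(clin, "subtype_full") <- subtype_full
  attr(clin, "realized_censoring") <- realized
  clin
}
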