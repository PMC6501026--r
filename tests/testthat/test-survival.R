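# Cox block models, Harrell's C, cross-validation, decomposition, KM.

test_that("Harrell's C enumerates the four-sample toy correctly", {
  est <- harrell_c(c(4, 3, 1, 2), 1:4, rep(1, 4))
  expect_equal(est$concordance, 5 / 6)
  expect_equal(est$comparable, 6)
})

test_that("risk reversing time order gives C = 1, constant risk C = 1/2", {
  tm <- sort(runif(50))
  expect_equal(harrell_c(-tm, tm, rep(1, 50))$percent, 100)
  expect_equal(harrell_c(rep(1, 50), tm, rep(1, 50))$concordance, 0.5)
})

test_that("Harrell's C matches exhaustive pair enumeration under censoring", {
  set.seed(1)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    tm <- sample(1:15, n, replace = TRUE)        # force ties in time
    ev <- rbinom(n, 1, 0.7)
    rk <- sample(1:8, n, replace = TRUE)         # force ties in risk
    if (sum(ev) == 0) next
    oc <- oracle_harrell_c(rk, tm, ev)
    if (is.na(oc)) next
    expect_equal(harrell_c(rk, tm, ev)$concordance, oc, tolerance = 1e-12)
  }
})

test_that("Harrell's C agrees with the survival package estimator", {
  set.seed(2)
  n <- 300
  tm <- rexp(n); ev <- rbinom(n, 1, 0.7); rk <- rnorm(n)
  mine <- harrell_c(rk, tm, ev)$concordance
  ref <- survival::concordance(survival::Surv(tm, ev) ~ rk,
                               reverse = TRUE)$concordance
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("C is invariant under strictly increasing transforms of risk", {
  set.seed(3)
  n <- 100
  tm <- rexp(n); ev <- rbinom(n, 1, 0.6); rk <- rnorm(n)
  c1 <- harrell_c(rk, tm, ev)$concordance
  expect_equal(harrell_c(exp(rk), tm, ev)$concordance, c1)
  expect_equal(harrell_c(100 + 3 * rk, tm, ev)$concordance, c1)
})

test_that("zero comparable pairs is an explicit error", {
  expect_error(harrell_c(c(1, 2), c(5, 5), c(0, 0)), "comparable")
})

test_that("Cox recovery: a binary covariate with true log hazard ratio 0.7", {
  set.seed(4)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, rate = exp(0.7 * x))
  cens <- rexp(n, rate = 0.4)
  ev <- as.integer(tm <= cens)
  y <- pmin(tm, cens)
  fit <- fit_cox_blocks(list(genetics = cbind(x = x)), y, ev)
  expect_lt(abs(unname(coef(fit)) - 0.7), 0.1)
  # the fitted partial likelihood improved and the score is near zero
  expect_gt(fit$loglik[2], fit$loglik[1])
  expect_lt(fit$convergence$score_norm, 1e-4)
})

test_that("duplicating every sample leaves the Cox estimate unchanged", {
  set.seed(5)
  n <- 150
  x <- rnorm(n)
  tm <- rexp(n, exp(0.5 * x)); ev <- rbinom(n, 1, 0.8)
  # Breslow tie handling makes duplication equivalent to doubled weights;
  # Efron treats the created ties differently by design
  f1 <- fit_cox_blocks(list(b = cbind(x = x)), tm, ev, ties = "breslow")
  idx <- rep(seq_len(n), 2)
  f2 <- fit_cox_blocks(list(b = cbind(x = x[idx])), tm[idx], ev[idx],
                       ties = "breslow")
  expect_equal(unname(coef(f2)), unname(coef(f1)), tolerance = 1e-6)
})

test_that("a covariate independent of survival has small effect and fair p", {
  set.seed(6)
  pvals <- replicate(40, {
    n <- 150
    x <- rnorm(n)
    tm <- rexp(n); ev <- rbinom(n, 1, 0.8)
    f <- fit_cox_blocks(list(b = cbind(x = x)), tm, ev)
    summary(f)$coefficients[1, "Pr(>|z|)"]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("block components sum exactly to the linear predictor", {
  coh <- small_cohort(n = 150, n_genes = 40)
  p <- fit_pca(coh$expression, 5)
  bl <- survival_blocks(coh$mutations, p, coh$clinical, n_pcs = 5)
  fit <- fit_cox_blocks(bl, coh$clinical$os_time, coh$clinical$os_event)
  expect_equal(rowSums(fit$components), fit$lp, tolerance = 1e-12)
})

test_that("cross-validated concordance is deterministic and fold-aggregated", {
  coh <- simulate_cohort(400, headline_truth(n_genes = 40, seed = 31L))
  p <- fit_pca(coh$expression, 5)
  bl <- survival_blocks(coh$mutations, p, coh$clinical, n_pcs = 5)
  r1 <- cv_concordance(bl, coh$clinical$os_time, coh$clinical$os_event,
                       seed = 7)
  r2 <- cv_concordance(bl, coh$clinical$os_time, coh$clinical$os_event,
                       seed = 7)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_equal(r1$mean, mean(r1$per_fold))
  expect_gte(min(r1$per_fold), 0)
  expect_lte(max(r1$per_fold), 1)
  expect_true(r1$mean >= min(r1$per_fold) && r1$mean <= max(r1$per_fold))
})

test_that("a pure-noise model cross-validates at chance level", {
  set.seed(8)
  n <- 800
  tm <- rexp(n); ev <- rbinom(n, 1, 0.7)
  bl <- list(noise = matrix(rnorm(n * 3), n, 3,
                            dimnames = list(NULL, c("a", "b", "c"))))
  r <- cv_concordance(bl, tm, ev, seed = 9)
  expect_gt(r$mean, 0.45)
  expect_lt(r$mean, 0.55)
})

test_that("comparing a model to itself gives zero difference and p near 1", {
  coh <- simulate_cohort(300, headline_truth(n_genes = 20, seed = 41L))
  p <- fit_pca(coh$expression, 3)
  bl <- survival_blocks(coh$mutations, p, coh$clinical, n_pcs = 3,
                        blocks = c("demographics", "stage"))
  cmp <- compare_models(bl, bl, coh$clinical$os_time,
                        coh$clinical$os_event, n_repeats = 2, seed = 10)
  expect_equal(cmp$difference, 0)
  expect_gt(cmp$p_value, 0.99)
})

test_that("an informative block beats its nested reduction", {
  coh <- simulate_cohort(1000, headline_truth(n_genes = 30, seed = 51L))
  p <- fit_pca(coh$expression, 5)
  full <- survival_blocks(coh$mutations, p, coh$clinical, n_pcs = 5)
  stage_only <- survival_blocks(coh$mutations, p, coh$clinical,
                                blocks = "stage")
  cmp <- compare_models(full, stage_only, coh$clinical$os_time,
                        coh$clinical$os_event, n_repeats = 3, seed = 11)
  expect_gt(cmp$difference, 0)
  expect_lt(cmp$p_value, 0.05)
})

test_that("risk contributions: planted 3:1 variance ratio, zero blocks, invariances", {
  set.seed(12)
  n <- 4000
  b1 <- rnorm(n, sd = sqrt(3))
  b2 <- rnorm(n, sd = 1)
  lp <- b1 + b2
  tm <- rexp(n, exp(lp)); ev <- rep(1L, n)
  fit <- fit_cox_blocks(list(one = cbind(v = b1), two = cbind(w = b2)),
                        tm, ev)
  rc <- risk_contributions(fit)
  expect_equal(sum(rc$fraction), 1, tolerance = 1e-9)
  expect_lt(abs(rc$fraction[rc$block == "one"] - 0.75), 0.03)
  expect_lt(abs(rc$fraction[rc$block == "two"] - 0.25), 0.03)
  # single-block model: contribution 1
  f1 <- fit_cox_blocks(list(solo = cbind(v = b1)), tm, ev)
  expect_equal(risk_contributions(f1)$fraction, 1, tolerance = 1e-12)
  # adding a constant to one block's component changes nothing
  comp <- fit$components
  comp[, "one"] <- comp[, "one"] + 100
  rc2 <- risk_contributions(fit, components = comp)
  expect_equal(rc2$fraction, rc$fraction, tolerance = 1e-9)
  # an all-zero-coefficient block contributes exactly zero
  fit0 <- fit
  fit0$components[, "two"] <- 0
  rc0 <- risk_contributions(fit0)
  expect_equal(rc0$fraction[rc0$block == "two"], 0, tolerance = 1e-12)
  expect_equal(rc0$fraction[rc0$block == "one"], 1, tolerance = 1e-12)
})

test_that("zero-variance linear predictor makes contributions undefined", {
  set.seed(13)
  tm <- rexp(20); ev <- rep(1L, 20)
  f <- fit_cox_blocks(list(b = cbind(x = rnorm(20))), tm, ev)
  f$components[] <- 0
  expect_error(risk_contributions(f), "zero-variance")
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- km_estimate(rep("all", 4), c(1, 2, 3, 4), rep(1, 4))
  expect_equal(km$curves$surv, c(0.75, 0.5, 0.25, 0))
  # censored toy {1+, 2, 3+}: only event at t=2 with 2 at risk
  km2 <- km_estimate(rep("all", 3), c(1, 2, 3), c(0, 1, 0))
  expect_equal(km2$curves$time, 2)
  expect_equal(km2$curves$surv, 0.5)
  expect_equal(km2$curves$n_risk, 2)
})

test_that("identical groups give a null log-rank test", {
  tm <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  ev <- rep(1, 10)
  g <- rep(c("A", "B"), each = 5)
  km <- km_estimate(g, tm, ev)
  expect_equal(km$logrank_chisq, 0, tolerance = 1e-10)
  expect_equal(km$logrank_p, 1, tolerance = 1e-9)
})

test_that("empty/missing groups are dropped with a warning", {
  expect_warning(km <- km_estimate(c("A", "A", NA, "B", "B"),
                                   c(1, 2, 3, 4, 5), c(1, 1, 1, 1, 0)),
                 "missing group")
  expect_equal(sort(unique(km$curves$group)), c("A", "B"))
})

test_that("Weibull-PH simulated data give unbiased Cox estimates", {
  # moderate replicate count; the acceptance suite runs the full version
  set.seed(14)
  est <- replicate(40, {
    n <- 500
    x <- rbinom(n, 1, 0.4)
    u <- runif(n)
    tm <- 10 * (-log(u) / exp(0.6 * x))^(1 / 1.3)
    cens <- quantile(tm, 0.7) * rexp(n)
    ev <- as.integer(tm <= cens)
    unname(coef(fit_cox_blocks(list(g = cbind(x = x)), pmin(tm, cens), ev)))
  })
  expect_lt(abs(mean(est) - 0.6), 3 * sd(est) / sqrt(length(est)))
})
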