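# Cohort generator: mutation model, expression model, survival layer.

test_that("independent mutations have pairwise odds ratios near 1", {
  tr <- make_truth(freqs = c(A = 0.5, B = 0.5, C = 0.5), seed = 11)
  mut <- generate_mutations(10000, tr)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    tab <- table(mut[, pair[1]], mut[, pair[2]]) + 0.5
    log_or <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
    expect_lt(abs(log_or), 0.15)
  }
})

test_that("realized driver counts match published frequencies at n = 488", {
  mut <- generate_mutations(488, default_truth(n_genes = 5, seed = 7))
  counts <- colSums(mut)
  # binomial 99% bounds around the published counts
  for (g in c("TP53", "KRAS")) {
    p <- luad_driver_freqs()[g]
    bounds <- qbinom(c(0.005, 0.995), 488, p)
    expect_gte(counts[[g]], bounds[1])
    expect_lte(counts[[g]], bounds[2])
  }
})

test_that("a planted exclusivity interaction is realized and matches the exact joint", {
  freqs <- luad_driver_freqs()
  theta <- matrix(0, 15, 15, dimnames = list(names(freqs), names(freqs)))
  theta["EGFR", "KRAS"] <- theta["KRAS", "EGFR"] <- -3
  tr <- make_truth(freqs = freqs, theta = theta, n_genes = 2, seed = 5)
  # exact model check: marginal pair log-odds from the enumerated joint
  d <- mutation_model_distribution(tr)
  jt <- sapply(0:1, function(a) sapply(0:1, function(b) {
    sum(d$prob[d$states[, "EGFR"] == a & d$states[, "KRAS"] == b])
  }))
  exact_lor <- log(jt[1, 1] * jt[2, 2] / (jt[2, 1] * jt[1, 2]))
  expect_equal(exact_lor, -3, tolerance = 1e-6)
  # sampled check
  mut <- generate_mutations(20000, tr)
  tab <- table(mut[, "EGFR"], mut[, "KRAS"]) + 0.5
  lor <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  expect_lt(abs(lor - (-3)), 0.3)
  # marginals survive calibration under the interaction
  expect_lt(abs(mean(mut[, "EGFR"]) - freqs["EGFR"]), 0.02)
  expect_lt(abs(mean(mut[, "KRAS"]) - freqs["KRAS"]), 0.02)
})

test_that("infeasible mutation models raise an error", {
  # near-hard three-way exclusivity at frequencies summing past 1 breaks
  # the field calibration, which must fail loudly rather than silently
  freqs <- c(A = 0.45, B = 0.45, C = 0.45)
  theta <- matrix(-700, 3, 3, dimnames = list(names(freqs), names(freqs)))
  diag(theta) <- 0
  tr <- make_truth(freqs = freqs, theta = theta)
  expect_error(generate_mutations(10, tr), "infeasible|converge")
})

test_that("noiseless expression with zero effects equals the intercepts", {
  tr <- make_truth(n_genes = 4, intercepts = c(1, 2, 3, 4), noise_sd = 1e-9,
                   seed = 3)
  mut <- generate_mutations(20, tr)
  y <- generate_expression(mut, tr)
  expect_equal(unname(y), matrix(rep(1:4, 20), 4, 20), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a single planted effect is recovered as a group-mean difference", {
  eff <- matrix(0, 2, 3)
  eff[1, 2] <- 2.0
  tr <- make_truth(freqs = c(A = 0.4, B = 0.3), n_genes = 3, effects = eff,
                   noise_sd = 0.01, seed = 9)
  mut <- generate_mutations(1000, tr)
  y <- generate_expression(mut, tr)
  diff <- mean(y[2, mut[, "A"] == 1]) - mean(y[2, mut[, "A"] == 0])
  expect_equal(diff, 2.0, tolerance = 0.01)
})

test_that("additive effects of opposite sign cancel in double mutants", {
  eff <- matrix(0, 2, 2)
  eff[1, 1] <- 1; eff[2, 1] <- -1
  tr <- make_truth(freqs = c(A = 0.5, B = 0.5), n_genes = 2, effects = eff,
                   noise_sd = 0.01, seed = 13)
  mut <- generate_mutations(2000, tr)
  y <- generate_expression(mut, tr)
  dbl <- mut[, "A"] == 1 & mut[, "B"] == 1
  wt <- mut[, "A"] == 0 & mut[, "B"] == 0
  expect_equal(mean(y[1, dbl]) - mean(y[1, wt]), 0, tolerance = 0.01)
})

test_that("with no effects or loadings, per-gene variance matches noise_sd^2", {
  tr <- make_truth(n_genes = 40, noise_sd = 0.7, seed = 21)
  mut <- generate_mutations(4000, tr)
  y <- generate_expression(mut, tr)
  v <- apply(y, 1, var)
  expect_equal(mean(v), 0.49, tolerance = 0.02)
  expect_true(all(abs(v - 0.49) < 0.1))
})

test_that("zero censor rate yields all-observed events", {
  tr <- make_truth(censor_rate = 0, seed = 2)
  mut <- generate_mutations(50, tr)
  y <- generate_expression(mut, tr)
  cl <- generate_clinical_and_survival(mut, y, tr)
  expect_true(all(cl$os_event == 1))
  expect_true(all(cl$rfs_event == 1))
})

test_that("with all block coefficients zero the true risk is uninformative", {
  tr <- make_truth(censor_rate = 0.3, seed = 6)
  mut <- generate_mutations(400, tr)
  y <- generate_expression(mut, tr)
  cl <- generate_clinical_and_survival(mut, y, tr)
  lp <- attr(cl, "true_lp")
  expect_true(all(lp == 0))
  # constant risk: every comparable pair is tied, C = 1/2 exactly
  expect_equal(harrell_c(lp, cl$os_time, cl$os_event)$concordance, 0.5)
})

test_that("the operating concordance of the true risk is stable in n", {
  tr <- headline_truth(n_genes = 10)
  mut <- generate_mutations(20000, tr)
  y <- generate_expression(mut, tr)
  cl <- generate_clinical_and_survival(mut, y, tr)
  c_big <- survival::concordance(
    survival::Surv(cl$os_time, cl$os_event) ~ attr(cl, "true_lp"),
    reverse = TRUE)$concordance
  tr2 <- headline_truth(n_genes = 10, seed = 99L)
  mut2 <- generate_mutations(2000, tr2)
  y2 <- generate_expression(mut2, tr2)
  cl2 <- generate_clinical_and_survival(mut2, y2, tr2)
  c_small <- harrell_c(attr(cl2, "true_lp"), cl2$os_time,
                       cl2$os_event)$concordance
  expect_equal(c_small, c_big, tolerance = 0.025)
})

test_that("higher true log-hazard gives stochastically shorter event times", {
  tr <- headline_truth(n_genes = 10)
  tr$censor_rate <- 0
  mut <- generate_mutations(4000, tr)
  y <- generate_expression(mut, tr)
  cl <- generate_clinical_and_survival(mut, y, tr)
  lp <- attr(cl, "true_lp")
  hi <- lp > median(lp)
  expect_lt(wilcox.test(cl$os_time[hi], cl$os_time[!hi],
                        alternative = "less")$p.value, 1e-10)
})

test_that("realized censoring tracks the target rate", {
  tr <- make_truth(censor_rate = 0.4, seed = 31)
  mut <- generate_mutations(2000, tr)
  y <- generate_expression(mut, tr)
  cl <- generate_clinical_and_survival(mut, y, tr)
  expect_equal(unname(attr(cl, "realized_censoring")["os"]), 0.4,
               tolerance = 0.03)
  expect_equal(mean(cl$os_event == 0), 0.4, tolerance = 0.03)
})

test_that("cohorts are fully deterministic under a fixed seed", {
  a <- simulate_cohort(80, default_truth(n_genes = 30, seed = 123))
  b <- simulate_cohort(80, default_truth(n_genes = 30, seed = 123))
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
})
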