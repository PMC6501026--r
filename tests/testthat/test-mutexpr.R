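# Per-gene additive models, empirical-Bayes moderation, target sets,
# correlations.

toy_fit <- function() {
  # 3 mutant (5,6,7) vs 3 wild-type (1,2,3): beta = 4, s2 = 1, d = 4
  mut <- matrix(c(1, 1, 1, 0, 0, 0), 6, 1,
                dimnames = list(paste0("s", 1:6), "M"))
  y <- matrix(c(5, 6, 7, 1, 2, 3), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  fit_gene_models(y, mut)
}

test_that("an exact linear gene is fitted without residual", {
  set.seed(1)
  mut <- matrix(rbinom(40, 1, 0.5), 20, 2,
                dimnames = list(paste0("s", 1:20), c("TP53", "KRAS")))
  y <- matrix(1 + 2 * mut[, "TP53"], 1, 20,
              dimnames = list("g1", rownames(mut)))
  f <- fit_gene_models(y, mut)
  expect_equal(unname(f$coefficients[1, "TP53"]), 2.0, tolerance = 1e-10)
  expect_equal(unname(f$coefficients[1, "(Intercept)"]), 1.0,
               tolerance = 1e-10)
  expect_equal(unname(f$r_squared[1]), 1.0, tolerance = 1e-10)
  expect_equal(unname(f$sigma2[1]), 0, tolerance = 1e-12)
})

test_that("the six-sample toy reproduces the hand OLS solution", {
  f <- toy_fit()
  expect_equal(unname(f$coefficients[1, "M"]), 4.0, tolerance = 1e-12)
  expect_equal(unname(f$sigma2[1]), 1.0, tolerance = 1e-12)
  expect_equal(f$df_residual, 4)
})

test_that("constant mutation columns are dropped with a warning", {
  set.seed(2)
  mut <- cbind(A = rbinom(20, 1, 0.5), B = rep(0, 20))
  rownames(mut) <- paste0("s", 1:20)
  y <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("g1", "g2"), rownames(mut)))
  expect_warning(f <- fit_gene_models(y, mut), "constant")
  expect_equal(f$mutation_cols, "A")
})

test_that("aliased design columns are dropped and recorded", {
  set.seed(3)
  a <- rbinom(30, 1, 0.5)
  mut <- cbind(A = a, B = a)                    # perfectly collinear
  rownames(mut) <- paste0("s", 1:30)
  y <- matrix(rnorm(60), 2, 30,
              dimnames = list(c("g1", "g2"), rownames(mut)))
  expect_warning(f <- fit_gene_models(y, mut), "aliased")
  expect_length(f$mutation_cols, 1)
  expect_length(f$dropped$aliased, 1)
})

test_that("forcing zero prior degrees of freedom reproduces classical F", {
  coh <- small_cohort(n = 80, n_genes = 50)
  f <- fit_gene_models(coh$expression, coh$mutations,
                       coh$clinical[, c("age", "gender")])
  fm <- moderate_statistics(f, prior_df = 0)
  k <- length(f$mutation_cols)
  f_classical <- ((f$rss_reduced - f$rss) / k) / f$sigma2
  expect_equal(unname(fm$moderated$F), unname(f_classical),
               tolerance = 1e-10)
  expect_equal(fm$moderated$df2, f$df_residual)
})

test_that("estimated variance prior agrees with the limma empirical-Bayes fit", {
  skip_if_not_installed("limma")
  coh <- small_cohort(n = 100, n_genes = 300, seed = 8)
  # keep only non-constant drivers so both designs are identical
  keep <- colSums(coh$mutations) > 0 & colSums(coh$mutations) < 100
  coh$mutations <- coh$mutations[, keep]
  f <- fit_gene_models(coh$expression, coh$mutations)
  fm <- moderate_statistics(f)
  sq <- limma::squeezeVar(f$sigma2, f$df_residual)
  expect_equal(fm$moderated$d0, sq$df.prior, tolerance = 0.02)
  expect_equal(fm$moderated$s0_2, sq$var.prior, tolerance = 0.02)
  expect_equal(unname(fm$moderated$s2_post), unname(sq$var.post),
               tolerance = 1e-6)
  # moderated t matches a full limma fit on the identical design
  design <- cbind(1, coh$mutations)
  lf <- limma::eBayes(limma::lmFit(coh$expression, design))
  expect_equal(unname(fm$moderated$coef_t),
               unname(lf$t[, colnames(coh$mutations)]), tolerance = 1e-6)
})

test_that("identical residual variances fall back to unmoderated statistics", {
  set.seed(4)
  mut <- cbind(A = rbinom(40, 1, 0.5))
  rownames(mut) <- paste0("s", 1:40)
  base <- rnorm(40)
  y <- t(sapply(1:20, function(i) i + base))    # same residuals every gene
  dimnames(y) <- list(paste0("g", 1:20), rownames(mut))
  f <- fit_gene_models(y, mut)
  expect_warning(fm <- moderate_statistics(f), "identical")
  expect_equal(fm$moderated$d0, 0)
})

test_that("BH q-values match a brute-force step-up on random p-vectors", {
  # spec'd hand example first
  expect_equal(p.adjust(c(0.001, 0.01, 0.02, 0.8), method = "BH"),
               c(0.004, 0.02, 0.08 / 3, 0.8), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(3:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("coefficients are recovered within their standard errors", {
  coh <- simulate_cohort(300, default_truth(n_genes = 80, seed = 10))
  f <- fit_gene_models(coh$expression, coh$mutations,
                       coh$clinical[, c("age", "gender")])
  beta_hat <- f$coefficients[, f$mutation_cols]
  beta_true <- t(coh$truth$effect_matrix)[, f$mutation_cols]
  se <- sqrt(f$sigma2) %o% f$stdev_unscaled[f$mutation_cols]
  covered <- abs(beta_hat - beta_true) <= 3 * se
  expect_gt(mean(covered), 0.97)
})

test_that("R-squared is invariant to affine rescaling of a gene", {
  coh <- small_cohort(n = 60, n_genes = 20)
  f1 <- fit_gene_models(coh$expression, coh$mutations)
  y2 <- coh$expression
  y2[3, ] <- 5 + 7 * y2[3, ]
  f2 <- fit_gene_models(y2, coh$mutations)
  expect_equal(f2$r_squared[3], f1$r_squared[3], tolerance = 1e-10)
})

test_that("genes built to a 40% variance budget yield that R-squared", {
  # var(beta*X) / (var(beta*X) + sigma^2) = 0.4 with X ~ Bern(p); a single
  # gene's R-squared has sampling sd near 0.03 at n = 488, so the check
  # averages over replicate planted genes
  p <- luad_driver_freqs()["TP53"]
  sigma <- 1
  beta <- sqrt(0.4 / 0.6 * sigma^2 / (p * (1 - p)))
  freqs <- luad_driver_freqs()
  n_rep <- 30
  eff <- matrix(0, 15, n_rep, dimnames = list(names(freqs), NULL))
  eff["TP53", ] <- beta
  tr <- make_truth(freqs = freqs, n_genes = n_rep, effects = eff,
                   noise_sd = sigma, seed = 77)
  mut <- generate_mutations(488, tr)
  y <- generate_expression(mut, tr)
  f <- fit_gene_models(y, mut)
  expect_lt(abs(mean(f$r_squared) - 0.40), 0.03)
  # predicted-vs-observed squared correlation tells the same story
  pv <- predicted_vs_observed(f, y, mut, "g1")
  expect_lt(abs(attr(pv, "r_squared") - unname(f$r_squared[1])), 0.02)
})

test_that("target sets recover a planted signature and respect thresholds", {
  freqs <- c(A = 0.4, B = 0.3)
  n_genes <- 200
  eff <- matrix(0, 2, n_genes)
  planted <- 1:50
  eff[1, planted] <- 0.8 * sample(c(-1, 1), 50, replace = TRUE)
  tr <- make_truth(freqs = freqs, n_genes = n_genes, effects = eff,
                   noise_sd = 0.5, seed = 19)
  mut <- generate_mutations(488, tr)
  y <- generate_expression(mut, tr)
  f <- moderate_statistics(fit_gene_models(y, mut))
  ts <- target_genes(f, "A", 0.01)
  hits <- as.integer(sub("g", "", ts$gene))
  expect_gte(sum(hits %in% planted) / 50, 0.95)          # recall
  expect_gte(mean(hits %in% planted), 0.9)               # precision
  # signs follow the planted direction
  sgn <- sign(eff[1, hits[hits %in% planted]])
  expect_equal(unname(sign(ts$log_fc[hits %in% planted])), unname(sgn))
  expect_equal(nrow(target_genes(f, "A", 0)), 0)
  expect_error(target_genes(f, "NOSUCH"), "unknown")
})

test_that("null cohorts are called at the nominal false-discovery rate", {
  tr <- make_truth(freqs = luad_driver_freqs(), n_genes = 400,
                   noise_sd = 1, seed = 23)
  mut <- generate_mutations(488, tr)
  y <- generate_expression(mut, tr)
  f <- moderate_statistics(fit_gene_models(y, mut))
  frac_called <- mean(f$moderated$q < 0.01)
  # <= 1% plus binomial slack at 400 genes
  expect_lte(frac_called, 0.01 + 3 * sqrt(0.01 * 0.99 / 400))
})

test_that("prediction works for planted and all-wild-type genotypes", {
  set.seed(6)
  mut <- cbind(A = rbinom(30, 1, 0.5))
  rownames(mut) <- paste0("s", 1:30)
  y <- matrix(2 + 3 * mut[, "A"], 1, 30,
              dimnames = list("g1", rownames(mut)))
  f <- fit_gene_models(y, mut)
  expect_equal(unname(predict(f, mut)["g1", ]), unname(y["g1", ]),
               tolerance = 1e-10)
  wt <- matrix(0, 2, 1, dimnames = list(c("n1", "n2"), "A"))
  expect_equal(unname(predict(f, wt)["g1", ]), c(2, 2), tolerance = 1e-10)
})

test_that("mutation-expression correlations behave like point-biserial/rank statistics", {
  set.seed(7)
  x <- rep(c(0, 1), each = 25)
  mut <- cbind(A = x)
  rownames(mut) <- paste0("s", 1:50)
  y <- matrix(ifelse(x == 1, 5, 1) + rnorm(50, sd = 1e-8), 1, 50,
              dimnames = list("g1", rownames(mut)))
  r <- mutation_expression_correlation(y, mut, "pearson")
  # brute-force point-biserial from the definition
  yy <- y[1, ]
  r_hand <- sum((yy - mean(yy)) * (x - mean(x))) /
    sqrt(sum((yy - mean(yy))^2) * sum((x - mean(x))^2))
  expect_equal(unname(r["A", "g1"]), r_hand, tolerance = 1e-10)
  expect_equal(unname(abs(r["A", "g1"])), 1, tolerance = 1e-6)
  # Spearman is invariant under a monotone transform
  y2 <- matrix(rnorm(50), 1, 50, dimnames = dimnames(y))
  s1 <- mutation_expression_correlation(y2, mut, "spearman")
  y3 <- exp(y2)
  s2 <- mutation_expression_correlation(y3, mut, "spearman")
  expect_equal(s1, s2, tolerance = 1e-12)
  # constant column gives NA
  mut0 <- cbind(A = x, B = rep(0, 50))
  rownames(mut0) <- rownames(mut)
  r0 <- mutation_expression_correlation(y, mut0)
  expect_true(is.na(r0["B", "g1"]))
})

test_that("independent mutation/expression columns have near-zero correlation", {
  set.seed(8)
  n <- 10000
  mut <- cbind(A = rbinom(n, 1, 0.3), B = rbinom(n, 1, 0.5))
  rownames(mut) <- paste0("s", 1:n)
  y <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("g", 1:5), rownames(mut)))
  r <- mutation_expression_correlation(y, mut)
  expect_gt(mean(abs(r) < 0.05), 0.99)
})
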