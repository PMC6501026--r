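# omicsurv

Integrative mutation–expression modelling and multi-block survival
prediction for tumor cohorts, with a fully parameterized synthetic-cohort
generator for validation.

## What it does, and for whom

Bulk tumor profiling studies routinely collect three views of the same
patients: a binary somatic driver-mutation matrix, a log-scale expression
matrix, and a clinical table with right-censored outcomes (overall survival,
OS; recurrence-free survival, RFS). `omicsurv` implements, as tested R
functions, the analysis chain that links them:

1. **Expression PCA** (`fit_pca`) — gene-centered decomposition with full
   explained-variance accounting, top-loading gene extraction
   (`top_loading_genes`) and a per-sample overlay of PC scores, mutation
   status and demographics (`overlay_table`).
2. **Additive mutation–expression models** (`fit_gene_models`) — per gene
   *g*, OLS of log expression on the shared design
   `intercept + 15 mutation indicators + confounders`, under the additive
   assumption that a tumor carrying several drivers shows the sum of their
   individual shifts:
   `y_g = a_g + X_mut β_g + X_conf γ_g + e_g`.
   Empirical-Bayes moderation (`moderate_statistics`) shrinks residual
   variances toward a scaled inverse chi-square prior fitted across genes
   and tests the mutation block with a moderated F (BH-adjusted);
   mutation-centric target-gene sets (`target_genes`) use per-coefficient
   moderated t statistics. Mutation-attributable variance is reported as
   sequential R² with confounders entered first (`explained_variance`).
3. **Pairwise mutation interactions** (`cooccurrence`, `target_overlap`) —
   co-occurrence/mutual-exclusivity log odds ratios with Fisher exact
   tests, and hypergeometric enrichment of overlapping target-gene sets.
4. **Phenotype LASSO** (`build_design`, `fit_lasso_cv`) — ℓ₁-penalized
   logistic models of histologic subtype, stage and demographics on the
   15 mutations plus the first 20 expression PCs, with stratified five-fold
   CV scored by deviance-based explained variance
   `R²(λ) = 1 − D_cv(λ)/D_null`, and a cross-phenotype importance table
   (`importance_heatmap`).
5. **Block Cox survival models** (`survival_blocks`, `fit_cox_blocks`) —
   proportional hazards on five covariate blocks (genetics, expression,
   pathology, demographics, stage), Harrell's concordance (`harrell_c`),
   cross-validated concordance in the quintile-train scheme
   (`cv_concordance`), paired model comparison with a sign-flip permutation
   test (`compare_models`), per-block risk decomposition
   (`risk_contributions`, fractions `f_b = cov(c_b, lp)/var(lp)` summing to
   one), and Kaplan–Meier stratification (`km_estimate`).
6. **Synthetic cohorts** (`sim_truth`, `default_truth`, `simulate_cohort`)
   — pairwise auto-logistic mutations calibrated to published LUAD driver
   frequencies, expression as additive shifts + latent factors + noise, and
   Weibull proportional-hazards survival whose log-hazard is a sum of block
   contributions, so every stage above has a parameter-recovery test
   surface.

Readers/writers for the standard TSV formats (including MAF-like input with
the non-silent and recurrence filters) live in `read_mutation_matrix`,
`read_expression_matrix`, `read_clinical_table`, `align_cohort`; a thin CLI
wrapper over the stage functions is installed at
`system.file("cli", "omicsurv.R", package = "omicsurv")`.

## Worked example

```r
library(omicsurv)
tr  <- default_truth(n_genes = 500, seed = 42)
coh <- simulate_cohort(488, tr)
coh
#> Synthetic multi-omic cohort
#>   samples: 488, drivers: 15, genes: 500
#>   events: OS 342/488, RFS 341/488 (censoring 30% / 30%)
#>   seed: 42

pca <- fit_pca(coh$expression, 20)
pca
#> Expression PCA: 20 components retained (of 488)
#>   explained: PC1 13.3%, PC2 11.8%, PC3 10.6%, PC4 1.2%, PC5 1.2%
#>   cumulative over retained: 50.9%

fits <- moderate_statistics(
  fit_gene_models(coh$expression, coh$mutations,
                  coh$clinical[, c("age", "gender")]))
summary(fits)
#> 500 genes, 488 samples
#> mutation-attributable R^2:
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> 0.008667 0.028973 0.039947 0.047725 0.055875 0.273080
#> genes with omnibus q < 0.01: 52 (min R^2 among them: 0.077)

bl  <- survival_blocks(coh$mutations, pca, coh$clinical, n_pcs = 20)
fit <- fit_cox_blocks(bl, coh$clinical$os_time, coh$clinical$os_event)
cv_concordance(bl, coh$clinical$os_time, coh$clinical$os_event, seed = 1)
#> Cross-validated Harrell's C (5 folds, quintile-train scheme)
#>   mean C = 60.1% (sd 2.5); per fold: 57.1%, 57.9%, 62.4%, 61.3%, 62.0%

risk_contributions(fit)
#> Risk-contribution decomposition
#>   genetics        16.0%  (marginal-drop dC = +0.014)
#>   expression      59.7%  (marginal-drop dC = +0.094)
#>   pathology        2.1%  (marginal-drop dC = +0.002)
#>   demographics     4.5%  (marginal-drop dC = +0.011)
#>   stage           17.8%  (marginal-drop dC = +0.031)
```

The three latent expression factors carry most of the planted prognostic
signal, so the expression block dominates the decomposition; the first
three PCs recover them (13.3 + 11.8 + 10.6% of variance) before the
spectrum flattens into noise.

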