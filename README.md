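# pgsmed

Polygenic scoring and counterfactual mediation for adolescent disordered
eating.

## The problem

Disordered-eating (DE) behaviors — fasting for weight loss, binge eating,
purging — and cognitions such as body dissatisfaction are common in
adolescent population cohorts and share phenotypic associations with
body-mass index (BMI). A natural genetic-epidemiology question is whether
common variants associated with BMI in large discovery GWAS are also
associated with DE in an independent adolescent cohort, and whether any such
association runs *through* measured childhood BMI (genetic liability →
higher childhood BMI → disordered eating) or acts directly.

`pgsmed` implements the full analytic chain for that question as a tested,
reusable R package:

1. **Summary-statistic QC and harmonization** — strand-ambiguous (A/T, C/G)
   SNP removal, allele-orientation matching against target genotypes (VCF or
   dosage matrix), with every drop logged.
2. **Clumping + thresholding PGS** — greedy LD clumping (smallest p per
   ±250 kb window, pruning r² > 0.1 in the target sample), then
   `score_i = Σ β_j d_ij` over variants passing a discovery p-value
   threshold, standardized to mean 0 / SD 1.
3. **Threshold optimization** — incremental (score-attributable) Nagelkerke
   pseudo-R² across a dense threshold grid, converted to the liability scale
   via `R²_liab = R²_obs · K²(1−K)² / (z² P(1−P))`, with permutation
   empirical p-values that account jointly for the number of thresholds
   tested and the optimization (`(1 + #[perm best p ≤ observed best p]) /
   (n_perm + 1)`).
4. **Association models** — logistic / linear fits of each outcome on the
   standardized score with sex and four ancestry PCs, odds ratios or betas
   per 1 SD, BH-FDR Q-values across phenotypes, sex-interaction and
   stratified fits.
5. **Longitudinal GLMM** — random-intercept logistic models with a
   score×age interaction (adaptive Gauss–Hermite quadrature) testing whether
   the association differs across ages 14/16/18.
6. **Causal mediation** — natural direct and indirect effects of a 1 SD
   score contrast through childhood zBMI: average causal mediation effect
   (ACME), average direct effect (ADE), and total effect as risk/mean
   differences, with bootstrap or quasi-Bayesian inference. The averaged
   decomposition satisfies `total = ADE + ACME` exactly.
7. **Synthetic cohort generator** — LD-blocked genotypes (per-block AR(1)
   Gaussian copula), a noisy discovery GWAS, phenotypes with the assumed
   PGS → zBMI → DE structure and calibrated prevalences, ordinal frequency
   items, and missing-at-random attrition driven by sex and the score. This
   is first-class, tested functionality: it defines the ground truth against
   which every stage is validated.

## Worked example

```r
library(pgsmed)
library(dplyr)

cfg <- sim_config(n_individuals = 4000, n_variants = 400, n_causal = 80, seed = 7)
study <- simulate_study(cfg)

panel <- study$sumstats |>
  remove_strand_ambiguous() |>
  harmonize(study$genotypes)
panel <- apply_clump(panel, clump(panel, study$genotypes))

scan <- pgs_threshold_scan(panel, study$genotypes, study$cohort, "fasting14",
                           grid = c(5e-8, 1e-5, 1e-3, 0.01, 0.1, 0.5, 1))
scan
#> <pgs_scan> fasting14 (binomial), n = 3102
#>   best threshold 5e-08: 49 SNPs, incremental R2 = 0.02526 (liability 0.09025), model p = 1.38e-08

scores <- score_pgs(panel, study$genotypes, scan$best_threshold)
d <- inner_join(study$cohort,
                tibble::tibble(id = scores$sample_id, std_score = scores$std_score),
                by = "id")
fit_association(d, "fasting14")
#>     outcome    n n_cases estimate conf.low conf.high      p.value    r2_liab
#> 1 fasting14 3102     221 1.486818 1.294937  1.707132 1.842934e-08 0.09024785

estimate_mediation(d, "fasting14", n_resamples = 500, seed = 1)
#> <mediation_fit> fasting14 ~ std_score via zbmi11 (binomial), n = 3102, bootstrap x 500
#>   total    0.0297  [0.0207, 0.0397]  p = 0.003992
#>   ade      0.0156  [0.0067, 0.0250]  p = 0.003992
#>   acme     0.0141  [0.0109, 0.0179]  p = 0.003992
#>   proportion mediated = 0.474
```

Reading the output: adolescents one SD higher on the BMI polygenic score
have 1.49 times the odds of monthly fasting at age 14 (Wald 95% CI
1.29–1.71); the score explains ~9% of liability-scale variance at the best
threshold in this synthetic cohort. The mediation decomposition says a 1 SD
score increase raises the absolute risk of fasting by 3.0 percentage points
in total, of which 1.4 points (47%) operate through childhood zBMI and 1.6
points directly. `tidy()`, `glance()` and `autoplot()` methods are available
on scan, GLMM and mediation objects, and `run_pipeline(run_config(...))`
executes the whole chain end to end with every artifact written to disk.

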