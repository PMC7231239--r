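---
title: "Methods: polygenic scoring and causal mediation for disordered eating"
author: "pgsmed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scoring and causal mediation for disordered eating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`pgsmed` implements the analytic chain used to ask whether common genetic
variants for body-mass index (BMI) are associated with adolescent disordered
eating (DE), and whether that association runs through measured childhood
BMI. The chain is: discovery GWAS summary statistics → strand QC and
allele harmonization against target genotypes → LD clumping →
threshold-optimized polygenic score (PGS) → covariate-adjusted association
with liability-scale variance explained and permutation empirical p-values →
longitudinal random-intercept models across ages 14/16/18 → counterfactual
mediation through childhood zBMI. Because individual-level cohort data of
this kind cannot be redistributed, the package ships a synthetic-data
generator that reproduces the statistical structure of such a study, and the
entire test suite runs against it.

## The polygenic score

The PGS is the classical clumping + thresholding (C+T) construction:

1. **Strand QC.** Variants with self-complementary allele pairs (A/T, C/G)
   are removed: their orientation cannot be resolved across genotyping
   strand conventions.
2. **Harmonization.** Variants are matched to the target panel by id. If
   the discovery effect allele equals the target ALT allele the dosage is
   used as-is; if it equals REF the dosage is flipped to `2 - d`; other
   allele configurations are dropped with a logged count.
3. **Clumping.** Greedy: the remaining variant with the smallest discovery
   p-value becomes an index SNP and every unpruned variant within ±250 kb
   with dosage r² > 0.1 against it is removed; repeat until exhausted. Ties
   on p are broken by smaller position, then lexicographic id, which makes
   the result invariant to input order. The window is interpreted as ±250 kb
   around the index (the common clumping convention); r² is computed in the
   target sample itself so the pipeline needs no external LD reference.
4. **Scoring.** `score_i = Σ_j β_j d_ij` over variants with discovery
   `p ≤ P_t`; a missing dosage is imputed as twice the in-sample effect-allele
   frequency. Scores are standardized to mean 0, SD 1 in the sample, so all
   reported effects are per 1 SD of PGS.

**Threshold optimization.** `pgs_threshold_scan()` evaluates a grid of
thresholds (default: `{5e-8, 1e-6, 1e-5}` plus 1e-4…1 in steps of 1e-4) and
reports, per threshold, the score-attributable (incremental) R²: Nagelkerke
pseudo-R² of the full model minus that of the covariate-only model for
binary outcomes, difference in squared multiple correlation for continuous
ones. Only thresholds at which the included-variant set changes are actually
refitted. Maximizing R² over a grid overfits; the accompanying
`permutation_empirical_p()` permutes the outcome vector (covariates stay
attached to their rows), reruns the entire grid scan per permutation, and
reports `(1 + #[perm best p ≤ observed best p]) / (n_perm + 1)`. The
comparison statistic is the best model p-value across the grid, so the
empirical p accounts jointly for the number of thresholds and the
optimization. The default `n_perm = 11000` matches large-scale practice; the
test suite uses 199 permutations, which is sufficient to demonstrate
uniformity under the null.

**Liability conversion.** For a binary outcome with population prevalence K
and sample case fraction P, observed-scale R² is multiplied by
`K²(1−K)² / (z² P(1−P))`, z the standard-normal density at the liability
threshold `qnorm(1−K)`. At `K = P = 0.5` the multiplier is exactly π/2, and
for any `K = P` it reduces to `K(1−K)/z²` — both closed forms are asserted
in the tests. In a population cohort no external prevalence is available, so
the default takes `K = P` (overridable via `prevalence_k`).

## Association and longitudinal models

`fit_association()` fits logistic (binary) or linear (continuous) models of
each outcome on the standardized score with biological sex and the first
four ancestry PCs as covariates, on complete cases; binary effects are odds
ratios per 1 SD with Wald CIs (the convention in PGS reporting; profile
likelihood would differ only in small samples), continuous effects are betas
per 1 SD of score on the raw outcome scale. BH false-discovery-rate Q-values
are applied across the phenotype family. `sex_interaction()` adds a
score×sex product term and returns sex-stratified companion fits.

`fit_glmm_interaction()` asks whether the score–outcome association differs
across ages: a logistic random-intercept model
`logit P(y_it) = β₀ + u_i + β₁ s_i + β₂ age_t + β₃ s_i·age_t + γ'x_i`,
`u_i ~ N(0, σ²)`, fitted by adaptive Gauss–Hermite quadrature (lme4, 9 nodes
by default, escalating to 25 on non-convergence; bobyqa optimizer, whose
convergence is more reliable than the default at these sample sizes). Age
enters linearly (centered at the first age, internally in 2-year units for
conditioning, reported per-year); a categorical coding is available. The
score is conventionally computed at `P_t = 1` so the same score is used at
every age. The integrated likelihood is validated against brute-force
numeric integration on a 30-person fixture.

## Counterfactual mediation

The mediation estimand follows the natural direct/indirect effect
decomposition. With treatment T (the standardized PGS, contrasted at 0 vs
1 SD), mediator M (zBMI at age 11) and outcome Y:

- mediator model: `M = α_m + aT + γ_m'X + ε`, `ε ~ N(0, σ²)`;
- outcome model: logistic or linear `Y ~ α_y + c'T + bM + γ_y'X`
  (no T×M interaction, matching the additive specification).

For every observed covariate profile the estimator draws potential mediators
`M(0), M(1)` from the fitted mediator model — one residual draw per profile
per resample, with the *same* draw used at both treatment levels, which
reduces Monte-Carlo variance without biasing the mean — and evaluates
model-implied outcome values (probabilities for binary outcomes, hence risk
differences) at all four (t, t′) combinations:

- `ACME(t) = mean_i[Y_i(t, M_i(1)) − Y_i(t, M_i(0))]`
- `ADE(t)  = mean_i[Y_i(1, M_i(t)) − Y_i(0, M_i(t))]`

Reported ACME and ADE average the two treatment arms, and the total effect
is their sum — with this averaging the decomposition `total = ADE + ACME`
is an exact identity, not an approximation, which the report asserts.
Inference is a nonparametric bootstrap (default 1000 resamples, refitting
both models per resample) with percentile CIs and two-sided resampling
p-values; a quasi-Bayesian mode (coefficient draws from the asymptotic
normal) is provided where refitting is too slow. Effects are evaluated over
the empirical covariate distribution of the analysis rows, not a reference
profile. Point estimates use 50 mediator draws so they are stable; resamples
use 1 draw each, absorbing that variance into the resampling distribution.

Identification requires sequential ignorability — no unmeasured
treatment–outcome, treatment–mediator, or mediator–outcome confounding given
the covariates, and no intermediate confounders. This is untestable; the
suite instead demonstrates the *consequence* of violating it (an omitted
mediator–outcome confounder inflates the ACME in the predicted direction).

Two oracles validate the estimator: in the all-linear model the ACME must
converge to the product of coefficients `a·b` and the ADE to `c'`
(Baron–Kenny equivalence), asserted at n = 20,000 within 0.02; for binary
outcomes the estimator is compared against brute-force numeric integration
of the logistic outcome over the true Normal mediator law at every covariate
profile, within 3 Monte-Carlo SEs at n = 10,000.

## The synthetic cohort generator

`simulate_study()` produces the three inputs the pipeline consumes, with a
known causal structure so every stage has a ground truth:

- **Genotypes.** One chromosome, fixed 5 kb spacing (so the 250 kb clumping
  window spans 50 adjacent variants). Haplotypes come from a per-block AR(1)
  Gaussian copula — latent normals thresholded at the Hardy–Weinberg allele
  frequency — giving controllable LD without external reference panels;
  blocks are independent.
- **Discovery GWAS.** Per-variant estimate = causal effect + noise with
  variance `1/(2·maf·(1−maf)·n_discovery)` (the asymptotic variance of a
  per-allele coefficient for a unit-variance trait); Wald p-values. A
  configurable fraction of variants is given strand-ambiguous allele pairs
  to exercise QC.
- **Cohort.** `zBMI = a·score + N(0,1)`, re-standardized within sex stratum
  (all BMI measurements are at one age). Binary outcomes follow
  `logit(p) = α + c'·score + b·zBMI + β_sex·sex`, with α calibrated by
  bisection on [−15, 15] (tolerance 1e-4 on the probability scale) so each
  realized prevalence matches its target. Five-level ordinal frequency items
  are generated from the same latent logistic propensity, with the
  once-a-month boundary at the calibrated intercept, so
  `dichotomize_frequency()` reproduces each binary outcome exactly; binge
  eating additionally requires a loss-of-control flag (P = 0.7 among
  overeaters, with the latent target scaled by 1/0.7 so the realized binge
  prevalence still hits its target). Continuous cognition outcomes are
  linear analogues with unit residual SD, with negative signs for thin-ideal
  internalization and external eating (their observed direction).
- **Missingness.** Outcome cells (the binary item, its frequency item and
  LOC flag together) are blanked with probability
  `plogis(qlogis(rate) + δ_sex·sex + δ_pgs·score)` — missing at random given
  sex and the score, exactly the mechanism under which complete-case
  analysis adjusting for those drivers is unbiased, which the suite checks.

**Default conditions.** The defaults describe the emulated study: 8654
individuals; binary prevalence targets from per-outcome case fractions
(fasting at 14 = 300/4584 ≈ 6.5%, through binge at 18 = 365/1910); discovery
sample 789,224; `h2_score = 0.25` (the raw true-score variance on the
discovery-trait scale, inside the 17–27% SNP-heritability band reported for
BMI, which fixes how many variants survive any given threshold);
`a_path = 0.35` (score–zBMI correlation ≈ 0.33, a strong but realistic
PGS→childhood-BMI path), `b_path = 0.55` log-odds per zBMI SD and
`c_prime = 0.20` direct log-odds per score SD. Those three values place the
synthetic study in the regime the real analyses report: implied fasting-14
OR per SD ≈ exp(0.20 + 0.55·0.33) ≈ 1.45, total risk difference ≈ 0.022
with roughly half mediated (≈ 0.011 + 0.011). Sex effect 1.2 log-odds
(female-predominant outcomes), base missingness 0.25. The per-person random
intercept `re_sd` defaults to 0 — the plain logistic generating model —
and is switched on explicitly where longitudinal correlation is the object
under test. The default panel is 1000 variants in blocks of 20 with
`within_block_r = 0.8` and 100 causal variants: large enough that clumping,
thresholding and scoring are non-trivial, small enough that the full chain
runs in seconds.

**What the generator does not emulate:** realistic human LD maps and allele
frequency spectra, imputation uncertainty, relatedness, the X chromosome,
population stratification beyond noise PCs, genotyping error, and
questionnaire measurement structure (the continuous scales are unit-SD
latents, not summed Likert items). Passing tests therefore validate the
statistical machinery, not robustness to those real-data complications.

## Numerical and design choices

- Positions are 1-based (VCF convention); window arithmetic is inclusive.
- Allele matching is case-insensitive; indels and multi-allelic records are
  dropped with logged counts (the analysis is SNP-only).
- Variants are matched between discovery and target by id; matching by
  position + alleles would be a straightforward extension.
- Monomorphic target variants get r² = 0 (with a warning) and are retained
  in scoring: their contribution is constant and absorbed by
  standardization.
- The threshold scan maximizes incremental R²; for a one-parameter nested
  comparison this coincides with minimizing the model p-value except in
  edge cases. Ties go to the smallest threshold.
- The permutation comparison statistic is the best model p-value (not best
  R²); the two orderings agree except in degenerate cases.
- Separation in a logistic association fit is reported as an error rather
  than silently penalized.
- The mediation outcome model excludes a treatment×mediator interaction,
  matching the additive specification; `mediator_draws` can be raised if the
  single-draw default is too noisy at small n.
- Mediation uses each outcome's best-fit threshold score by default
  (configurable), since the analysis is exploratory and downstream of the
  scan.
- All randomness flows from one integer seed per entry point; stage-level
  substreams are derived from fixed labels so stages can be re-run in
  isolation with identical results. RNG state is restored on exit, so
  package calls do not perturb the caller's stream.

## Problem sizes used in validation

The suite exercises the same properties the study-scale analysis relies on,
at sizes chosen to keep the complete run in minutes on one core: clumping
equivalence on 200 random ≤12-variant fixtures against an exhaustive
reference; OR-per-SD recovery at n = 5000 over 100 replicates (mean OR in
[1.35, 1.45], CI coverage ≥ 0.92); permutation uniformity over 200 procedure
replicates at n = 400, a 50-point grid and 199 permutations — alongside the
demonstration that the naive best-fit p is anti-conservative, which is the
reason the empirical p exists; GLMM interaction type-I error over 200
replicates of 400 persons × 3 ages; mediation oracles at n = 20,000 (linear,
1000 bootstrap resamples) and n = 10,000 (binary). The acceptance script
reruns the full chain on the default 8654-person study with a 51-point grid,
199 permutations and 500 bootstrap resamples.

## Known limitations

- The liability conversion assumes the sample case fraction estimates the
  population prevalence (K = P) unless told otherwise; ascertained samples
  need an explicit `prevalence_k`.
- Wald CIs can misbehave with very sparse outcomes; the rarest default
  outcome (1.6%) is well within safe territory at n ≈ 8654 but not at small
  n.
- The bootstrap refits both mediation models per resample; for very large
  cohorts the quasi-Bayesian mode is an order of magnitude faster with
  near-identical intervals in our checks.
- No shrinkage/continuous-weight PGS methods, external LD references, or
  genome-build liftover; no multiple imputation or inverse-probability
  weighting for attrition (complete-case analysis with MAR-relevant
  covariates is the supported design).
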