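#' Simulation settings for the synthetic study
#'
#' Bundles every knob of the synthetic data generator: an LD-blocked genotype
#' panel, a discovery GWAS re-estimated on `n_discovery` notional samples, and
#' an adolescent cohort in which a latent genetic score raises childhood zBMI
#' (`a_path`), zBMI raises disordered-eating risk (`b_path`), and the score
#' retains a direct effect (`c_prime`). Defaults emulate the structure of a
#' large UK birth-cohort analysis: 8654 individuals, outcome prevalences set
#' from per-outcome case fractions (fasting at 14 about 6.5%), a discovery
#' sample of 789,224, and path coefficients in the regime where the implied
#' odds ratio per score SD is about 1.4 and roughly half of the risk
#' difference is mediated.
#'
#' @param n_individuals Target-cohort size.
#' @param n_variants Number of simulated variants on one chromosome, spaced
#'   5 kb apart.
#' @param n_causal Number of variants with non-zero effects on the discovery
#'   trait.
#' @param ld_block_size Variants per LD block; blocks are mutually
#'   independent.
#' @param within_block_r Latent adjacent-variant correlation inside a block
#'   (AR(1) Gaussian copula), in `[0, 1)`.
#' @param maf_range Lower/upper bound of the uniform minor-allele-frequency
#'   draw, in `(0, 0.5]`.
#' @param h2_score Variance of the raw true genetic score on the discovery
#'   trait scale; scales causal effect sizes and therefore discovery GWAS
#'   power.
#' @param a_path Mediator (zBMI) change in SD units per 1 SD of the true
#'   score.
#' @param b_path Outcome effect per 1 SD of zBMI: log-odds for binary
#'   outcomes, outcome units for continuous ones.
#' @param c_prime Direct outcome effect per 1 SD of the true score, on the
#'   same scales as `b_path`.
#' @param sex_effect Additive female log-odds effect on binary outcomes
#'   (disordered eating is strongly female-predominant).
#' @param sex_effect_cont Additive female effect on continuous outcomes.
#' @param prevalence_targets Named vector of baseline prevalences for the
#'   binary outcomes; names define the outcome roster.
#' @param n_discovery Effective discovery GWAS sample size.
#' @param ambiguous_fraction Fraction of variants given strand-ambiguous
#'   (A/T or C/G) allele pairs, for QC testing.
#' @param missing_rate Base probability that an outcome cell is set missing
#'   by [apply_mar_missingness()].
#' @param loc_prob Probability that an overeating episode is accompanied by
#'   loss of control (used for the binge-eating definition).
#' @param re_sd SD of a per-person, per-behavior random intercept shared
#'   across ages (0 = the plain logistic generating model).
#' @param seed Single integer seed; all generator substreams derive from it.
#'
#' @return A `sim_config` list, validated.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 200, n_variants = 50, n_causal = 10)
#' geno <- simulate_genotypes(cfg)
#' dim(geno$dosage)
sim_config <- function(n_individuals = 8654,
                       n_variants = 1000,
                       n_causal = 100,
                       ld_block_size = 20,
                       within_block_r = 0.8,
                       maf_range = c(0.05, 0.5),
                       h2_score = 0.25,
                       a_path = 0.35,
                       b_path = 0.55,
                       c_prime = 0.20,
                       sex_effect = 1.2,
                       sex_effect_cont = 0.3,
                       prevalence_targets = default_prevalences(),
                       n_discovery = 789224,
                       ambiguous_fraction = 0.05,
                       missing_rate = 0.25,
                       loc_prob = 0.7,
                       re_sd = 0,
                       seed = 1L) {
  cfg <- list(
    n_individuals = check_count(n_individuals, "n_individuals"),
    n_variants = check_count(n_variants, "n_variants"),
    n_causal = check_count(n_causal, "n_causal", min = 0),
    ld_block_size = check_count(ld_block_size, "ld_block_size"),
    within_block_r = within_block_r,
    maf_range = maf_range,
    h2_score = h2_score,
    a_path = a_path,
    b_path = b_path,
    c_prime = c_prime,
    sex_effect = sex_effect,
    sex_effect_cont = sex_effect_cont,
    prevalence_targets = prevalence_targets,
    n_discovery = check_count(n_discovery, "n_discovery"),
    ambiguous_fraction = check_prob(ambiguous_fraction, "ambiguous_fraction",
                                    open = FALSE),
    missing_rate = missing_rate,
    loc_prob = check_prob(loc_prob, "loc_prob"),
    re_sd = re_sd,
    seed = check_count(seed, "seed", min = 0)
  )
  if (cfg$n_causal > cfg$n_variants) {
    abort("`n_causal` must not exceed `n_variants`.",
          class = "pgsmed_config_error")
  }
  if (!is.numeric(within_block_r) || within_block_r < 0 || within_block_r >= 1) {
    abort("`within_block_r` must lie in [0, 1).", class = "pgsmed_config_error")
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair in (0, 0.5].",
          class = "pgsmed_config_error")
  }
  if (any(prevalence_targets <= 0) || any(prevalence_targets >= 1) ||
      is.null(names(prevalence_targets)) || anyDuplicated(names(prevalence_targets))) {
    abort("`prevalence_targets` must be uniquely named probabilities in (0, 1).",
          class = "pgsmed_config_error")
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).", class = "pgsmed_config_error")
  }
  if (re_sd < 0) abort("`re_sd` must be >= 0.", class = "pgsmed_config_error")
  structure(cfg, class = "sim_config")
}

#' Default binary-outcome prevalences
#'
#' Baseline prevalences for the eight binary disordered-eating outcomes
#' (behavior x age), computed as case counts over per-outcome assessed sample
#' sizes in the adolescent cohort the generator emulates (e.g. fasting at age
#' 14: 300 cases of 4584 assessed).
#'
#' @return Named numeric vector of prevalences.
#' @export
default_prevalences <- function() {
  c(fasting14 = 300 / 4584, fasting16 = 516 / 3844, fasting18 = 143 / 2586,
    binge14 = 257 / 4144, binge16 = 434 / 3336, binge18 = 365 / 1910,
    purge16 = 237 / 3871, purge18 = 166 / 2582)
}

#' Continuous disordered-eating cognition outcomes
#'
#' Names and effect directions of the five continuous cognition scales
#' measured at age 14. Thin-ideal internalization and external eating are
#' generated with negative score/zBMI effects, matching their observed
#' negative association with BMI.
#'
#' @return Named numeric vector of signs (+1/-1) keyed by outcome name.
#' @export
continuous_outcomes <- function() {
  c(thin_ideal14 = -1, body_dissat14 = 1, restrained14 = 1,
    emotional14 = 1, external14 = -1)
}

#' Ordinal frequency response levels
#'
#' The five past-year frequency levels used for the behavioral items, from
#' which binary outcomes are derived by [dichotomize_frequency()].
#'
#' @return Character vector of the five levels, ordered.
#' @export
de_frequency_levels <- function() {
  c("Never", "Less than once a month", "1-3 times a month",
    "Once a week", "2 or more times a week")
}

#' Simulate an LD-blocked genotype panel
#'
#' Generates biallelic dosages in `{0, 1, 2}` for `n_individuals` x
#' `n_variants` on a single chromosome with fixed 5 kb spacing. Haplotypes
#' are drawn from a per-block AR(1) Gaussian copula (latent normals
#' thresholded at the Hardy-Weinberg allele frequency), so adjacent variants
#' within a block are correlated at roughly `within_block_r` on the latent
#' scale and blocks are independent.
#'
#' @param config A [sim_config()].
#' @return A `genotype_matrix`: list with `dosage` (numeric matrix, samples
#'   x variants), `variants` (tibble: snp_id, chrom, pos, ref, alt, maf) and
#'   `samples` (character ids).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_variants
  r <- config$within_block_r

  with_substream(config$seed, "genotypes", {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    thr <- qnorm(maf)
    block <- rep(seq_len(ceiling(m / config$ld_block_size)),
                 each = config$ld_block_size)[seq_len(m)]

    draw_haplotype <- function() {
      z <- matrix(rnorm(n * m), nrow = n, ncol = m)
      if (r > 0 && m > 1) {
        s <- sqrt(1 - r^2)
        for (j in 2:m) {
          if (block[j] == block[j - 1]) {
            z[, j] <- r * z[, j - 1] + s * z[, j]
          }
        }
      }
      # threshold each column at the allele frequency quantile
      sweep(z, 2, thr, `<`) * 1L
    }
    dosage <- draw_haplotype() + draw_haplotype()

    alleles <- assign_alleles(m, config$ambiguous_fraction)
    snp_id <- sprintf("snp%05d", seq_len(m))
    dimnames(dosage) <- list(sprintf("id%05d", seq_len(n)), snp_id)
    genotype_matrix(
      dosage = dosage,
      variants = tibble(
        snp_id = snp_id, chrom = "1", pos = 5000L * seq_len(m),
        ref = alleles$ref, alt = alleles$alt, maf = maf
      )
    )
  })
}

# draw ref/alt pairs with an exact count of strand-ambiguous variants
assign_alleles <- function(m, ambiguous_fraction) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_amb <- round(ambiguous_fraction * m)
  amb_idx <- if (n_amb > 0) sample.int(m, n_amb) else integer(0)
  ref <- sample(bases, m, replace = TRUE)
  alt <- character(m)
  for (j in seq_len(m)) {
    alt[j] <- if (j %in% amb_idx) {
      comp[[ref[j]]]
    } else {
      sample(setdiff(bases, c(ref[j], comp[[ref[j]]])), 1)
    }
  }
  list(ref = ref, alt = alt)
}

#' Construct a genotype matrix object
#'
#' @param dosage Numeric matrix (samples x variants), values in `[0, 2]` or
#'   `NA`.
#' @param variants Tibble with columns snp_id, chrom, pos, ref, alt (and
#'   optionally maf), one row per dosage column.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  if (!anyNA(variants$chrom) &&
      is.unsorted(variants$pos[variants$chrom == variants$chrom[1]])) {
    # positions must be non-decreasing within a chromosome
    ord <- order(variants$chrom, variants$pos)
    if (!identical(ord, seq_len(nrow(variants)))) {
      abort("variant positions must be non-decreasing within chromosome",
            class = "pgsmed_input_error")
    }
  }
  structure(
    list(dosage = dosage, variants = as_tibble(variants),
         samples = rownames(dosage) %||% sprintf("id%05d", seq_len(nrow(dosage)))),
    class = "genotype_matrix"
  )
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants, chrom %s, %.3f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), paste(unique(x$variants$chrom), collapse = ","),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Draw the true genetic model
#'
#' Picks `n_causal` causal variants and draws their per-allele effects so the
#' raw true score has variance `h2_score` on the discovery-trait scale; all
#' other variants have effect exactly zero. The realized per-individual true
#' score (raw and standardized) is returned with the path coefficients.
#'
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return A `true_model` list: `causal_betas` (named, length = n variants),
#'   `true_score`, `true_score_std`, `a_path`, `b_path`, `c_prime`.
#' @export
simulate_true_model <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  m <- ncol(genotypes$dosage)
  with_substream(config$seed, "truemodel", {
    beta <- numeric(m)
    if (config$n_causal > 0) {
      idx <- sort(sample.int(m, config$n_causal))
      maf <- genotypes$variants$maf %||% (colMeans(genotypes$dosage, na.rm = TRUE) / 2)
      # scale so var(sum beta_j g_j) ~ h2_score under linkage equilibrium
      tau2 <- config$h2_score / sum(2 * maf[idx] * (1 - maf[idx]))
      beta[idx] <- rnorm(config$n_causal, 0, sqrt(tau2))
    }
    names(beta) <- genotypes$variants$snp_id
    raw <- as.vector(genotypes$dosage %*% beta)
    std <- if (sd(raw) > 0) as.vector(scale(raw)) else raw
    structure(
      list(causal_betas = beta, true_score = raw, true_score_std = std,
           a_path = config$a_path, b_path = config$b_path,
           c_prime = config$c_prime),
      class = "true_model"
    )
  })
}

#' Simulate discovery GWAS summary statistics
#'
#' Re-estimates each variant's effect as the true causal effect plus
#' estimation noise with variance `1 / (2 * maf * (1 - maf) * n_discovery)`,
#' the asymptotic variance of a per-allele regression coefficient for a
#' unit-variance trait. Two-sided p-values come from the Wald statistic. The
#' effect allele is the target panel's ALT allele.
#'
#' @param genotypes A `genotype_matrix` (supplies the variant panel and
#'   allele frequencies).
#' @param true_model A [simulate_true_model()] result on the same panel.
#' @param n_discovery Effective discovery sample size (> 0).
#' @param seed Integer seed for the estimation noise.
#' @param ambiguous_fraction Optionally re-draw allele pairs so that exactly
#'   `round(ambiguous_fraction * n_variants)` variants are strand-ambiguous;
#'   `NULL` keeps the panel's alleles.
#' @return A `sumstats` tibble: snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, p.
#' @export
simulate_discovery_sumstats <- function(genotypes, true_model,
                                        n_discovery = 789224,
                                        seed = 1L,
                                        ambiguous_fraction = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(true_model, "true_model"))
  n_discovery <- check_count(n_discovery, "n_discovery")
  v <- genotypes$variants
  maf <- v$maf %||% (colMeans(genotypes$dosage, na.rm = TRUE) / 2)

  with_substream(seed, "sumstats", {
    se <- 1 / sqrt(2 * maf * (1 - maf) * n_discovery)
    beta_hat <- unname(true_model$causal_betas) + rnorm(length(se), 0, se)
    z <- beta_hat / se
    p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)

    ref <- v$ref
    alt <- v$alt
    if (!is.null(ambiguous_fraction)) {
      al <- assign_alleles(nrow(v), ambiguous_fraction)
      ref <- al$ref
      alt <- al$alt
    }
    new_sumstats(tibble(
      snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
      effect_allele = alt, other_allele = ref,
      eaf = maf, beta = beta_hat, se = se, p = p
    ))
  })
}

new_sumstats <- function(x) {
  class(x) <- c("sumstats", class(tibble()))
  x
}

#' Simulate the adolescent cohort table
#'
#' Builds phenotypes with the assumed causal structure. The mediator is
#' `zbmi11 = a_path * standardized true score + N(0, 1)`, re-standardized to
#' mean 0 / SD 1 within sex stratum (all BMI measurements are at one age).
#' Each binary outcome follows `logit(p) = alpha + c_prime * score + b_path *
#' zbmi + sex_effect * sex` with `alpha` calibrated by bisection so the
#' realized prevalence matches its target; an ordinal five-level frequency
#' item is generated from the same latent logistic propensity so that
#' [dichotomize_frequency()] reproduces the binary outcome exactly. Binge
#' eating additionally requires a loss-of-control flag. Continuous cognition
#' outcomes are linear analogues with unit residual SD, signed per
#' [continuous_outcomes()].
#'
#' @param genotypes A `genotype_matrix`.
#' @param true_model The matching `true_model`.
#' @param config The [sim_config()].
#' @return A tibble with columns: id, sex (1 = female), pc1-pc4, true_score
#'   (standardized), zbmi11, one binary + one `_freq` column per binary
#'   outcome (plus `_loc` for binge), and the five continuous outcomes.
#'   Calibrated intercepts are attached as attribute `"alphas"`.
#' @export
simulate_cohort <- function(genotypes, true_model, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(true_model, "true_model"),
            inherits(config, "sim_config"))
  n <- nrow(genotypes$dosage)
  score <- true_model$true_score_std

  with_substream(config$seed, "cohort", {
    sex <- rbinom(n, 1, 0.5)
    pcs <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("pc", 1:4)))

    zbmi <- config$a_path * score + rnorm(n)
    # re-standardize within sex stratum (single measurement age)
    for (s in unique(sex)) {
      i <- sex == s
      zbmi[i] <- (zbmi[i] - mean(zbmi[i])) / sd(zbmi[i])
    }

    out <- tibble(id = genotypes$samples, sex = sex,
                  pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3], pc4 = pcs[, 4],
                  true_score = score, zbmi11 = zbmi)

    eta_base <- config$c_prime * score + config$b_path * zbmi +
      config$sex_effect * sex
    behaviors <- sub("[0-9]+$", "", names(config$prevalence_targets))
    re_draws <- list()
    alphas <- numeric(0)

    for (k in seq_along(config$prevalence_targets)) {
      nm <- names(config$prevalence_targets)[k]
      target <- config$prevalence_targets[[k]]
      is_binge <- startsWith(behaviors[k], "binge")
      target_lat <- if (is_binge) target / config$loc_prob else target
      if (target_lat >= 1) {
        abort(sprintf("prevalence target for %s unreachable given loc_prob", nm),
              class = "pgsmed_calibration_error")
      }

      eta <- eta_base
      if (config$re_sd > 0) {
        beh <- behaviors[k]
        if (is.null(re_draws[[beh]])) re_draws[[beh]] <- rnorm(n, 0, config$re_sd)
        eta <- eta + re_draws[[beh]]
      }
      alpha <- calibrate_intercept(eta, target_lat)
      alphas[nm] <- alpha

      u <- alpha + eta + rlogis(n)
      freq <- cut(u, breaks = c(-Inf, -1.5, 0, 1, 2, Inf),
                  labels = de_frequency_levels(), right = TRUE)
      y <- as.integer(u > 0)
      if (is_binge) {
        loc <- rbinom(n, 1, config$loc_prob)
        out[[paste0(nm, "_loc")]] <- loc
        y <- as.integer(y == 1L & loc == 1L)
      }
      out[[nm]] <- y
      out[[paste0(nm, "_freq")]] <- as.character(freq)
    }

    for (nm in names(continuous_outcomes())) {
      sgn <- continuous_outcomes()[[nm]]
      out[[nm]] <- sgn * (config$c_prime * score + config$b_path * zbmi) +
        config$sex_effect_cont * sex + rnorm(n)
    }

    attr(out, "alphas") <- alphas
    out
  })
}

# bisection on the logistic intercept so mean(plogis(alpha + eta)) hits the
# target prevalence; interval [-15, 15], tolerance 1e-4 on probabilities
calibrate_intercept <- function(eta, target, lower = -15, upper = 15,
                                tol = 1e-4) {
  f <- function(a) mean(plogis(a + eta)) - target
  if (f(lower) > 0 || f(upper) < 0) {
    abort("prevalence target not bracketed by intercept range [-15, 15]",
          class = "pgsmed_calibration_error")
  }
  while (upper - lower > 1e-10) {
    mid <- (lower + upper) / 2
    if (abs(f(mid)) < tol) return(mid)
    if (f(mid) > 0) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

#' Dichotomize an ordinal frequency response
#'
#' Maps the five-level past-year frequency item to the binary outcome used in
#' analysis: 1 if the behavior occurred at least once a month ("1-3 times a
#' month" or more often). For binge eating, supply the loss-of-control flag;
#' a positive response then additionally requires `loss_of_control == 1`.
#'
#' @param freq Character/factor vector in [de_frequency_levels()]; `NA`
#'   propagates.
#' @param loss_of_control Optional 0/1/logical vector of the same length.
#' @return Integer 0/1 vector (with `NA` where inputs are missing).
#' @export
#' @examples
#' dichotomize_frequency(c("Never", "1-3 times a month"))
dichotomize_frequency <- function(freq, loss_of_control = NULL) {
  freq <- as.character(freq)
  lv <- de_frequency_levels()
  bad <- !is.na(freq) & !(freq %in% lv)
  if (any(bad)) {
    abort(sprintf("unknown frequency level(s): %s",
                  paste(unique(freq[bad]), collapse = ", ")),
          class = "pgsmed_validation_error")
  }
  out <- as.integer(match(freq, lv) >= 3L)
  if (!is.null(loss_of_control)) {
    stopifnot(length(loss_of_control) == length(freq))
    out <- as.integer(out == 1L & as.integer(loss_of_control) == 1L)
    out[is.na(freq) | is.na(loss_of_control)] <- NA_integer_
  }
  out
}

#' Impose missing-at-random attrition on outcome cells
#'
#' Sets outcome cells missing with probability
#' `plogis(qlogis(missing_rate) + delta_sex * sex + delta_score * score)`,
#' i.e. missingness driven only by sex and the (standardized) genetic score,
#' the two drivers a complete-case analysis adjusting for them can absorb.
#' Covariates, the mediator and ids are never blanked. The per-cell
#' missingness indicator matrix is attached as attribute `"miss_pattern"`.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param missing_rate Base missingness probability in `[0, 1)`.
#' @param delta_sex,delta_score Log-odds shifts per unit sex / per SD score.
#' @param score_col Column holding the standardized score driving attrition.
#' @param seed Integer seed.
#' @return The cohort with `NA`s in outcome columns.
#' @export
apply_mar_missingness <- function(cohort, missing_rate, delta_sex = 0,
                                  delta_score = 0, score_col = "true_score",
                                  seed = 1L) {
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).", class = "pgsmed_config_error")
  }
  if (missing_rate == 0 && delta_sex == 0 && delta_score == 0) return(cohort)
  stopifnot(score_col %in% names(cohort), "sex" %in% names(cohort))

  base_cols <- c("id", "sex", "pc1", "pc2", "pc3", "pc4", "true_score", "zbmi11",
                 score_col)
  outcome_cols <- setdiff(names(cohort), base_cols)
  p <- plogis(qlogis(missing_rate) + delta_sex * cohort$sex +
                delta_score * cohort[[score_col]])

  with_substream(seed, "mar", {
    miss <- matrix(FALSE, nrow(cohort), length(outcome_cols),
                   dimnames = list(NULL, outcome_cols))
    # binary outcome, its frequency item and its LOC flag go missing together
    stems <- unique(sub("_(freq|loc)$", "", outcome_cols))
    for (stem in stems) {
      cols <- outcome_cols[outcome_cols == stem |
                             startsWith(outcome_cols, paste0(stem, "_"))]
      hit <- runif(nrow(cohort)) < p
      for (cl in cols) {
        miss[hit, cl] <- TRUE
        cohort[[cl]][hit] <- NA
      }
    }
    attr(cohort, "miss_pattern") <- miss
    cohort
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_true_model()], [simulate_discovery_sumstats()],
#' [simulate_cohort()] and (optionally) [apply_mar_missingness()] under one
#' configuration.
#'
#' @param config A [sim_config()].
#' @param mar Apply the configured missingness mechanism (default TRUE when
#'   `missing_rate > 0`).
#' @return List with elements `genotypes`, `true_model`, `sumstats`,
#'   `cohort`, `config`.
#' @export
simulate_study <- function(config = sim_config(), mar = config$missing_rate > 0) {
  genotypes <- simulate_genotypes(config)
  true_model <- simulate_true_model(genotypes, config)
  sumstats <- simulate_discovery_sumstats(
    genotypes, true_model, n_discovery = config$n_discovery,
    seed = derive_seed(config$seed, "sumstats-stage")
  )
  cohort <- simulate_cohort(genotypes, true_model, config)
  if (mar) {
    cohort <- apply_mar_missingness(
      cohort, config$missing_rate, delta_sex = -0.3, delta_score = 0.15,
      seed = derive_seed(config$seed, "mar-stage")
    )
  }
  list(genotypes = genotypes, true_model = true_model, sumstats = sumstats,
       cohort = cohort, config = config)
}
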