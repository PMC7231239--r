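# synthetic-data generator: genotypes, discovery GWAS, cohort, missingness

test_that("genotype simulation respects range, dimensions and determinism", {
  cfg <- sim_config(n_individuals = 4, n_variants = 3, n_causal = 1,
                    within_block_r = 0, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g$dosage), c(4, 3))
  expect_true(all(g$dosage %in% 0:2))
  expect_equal(g$variants$pos, c(5000L, 10000L, 15000L))

  g2 <- simulate_genotypes(cfg)
  expect_identical(g$dosage, g2$dosage)
  expect_identical(g$variants, g2$variants)

  g3 <- simulate_genotypes(sim_config(n_individuals = 4, n_variants = 3,
                                      n_causal = 1, within_block_r = 0, seed = 2))
  expect_false(identical(g$dosage, g3$dosage))
})

test_that("LD blocks produce within-block correlation and cross-block independence", {
  cfg <- sim_config(n_individuals = 2000, n_variants = 40, n_causal = 5,
                    ld_block_size = 4, within_block_r = 0.9,
                    maf_range = c(0.2, 0.5), seed = 3)
  g <- simulate_genotypes(cfg)
  r2 <- cor(g$dosage)^2
  block <- rep(seq_len(10), each = 4)
  same <- outer(block, block, `==`) & upper.tri(r2)
  cross <- !outer(block, block, `==`) & upper.tri(r2)
  expect_gt(mean(r2[same]) - mean(r2[cross]), 0.3)
  expect_lt(mean(r2[cross]), 0.01)
})

test_that("allele frequencies land inside the configured range", {
  cfg <- sim_config(n_individuals = 3000, n_variants = 60, n_causal = 5,
                    maf_range = c(0.1, 0.3), seed = 4)
  g <- simulate_genotypes(cfg)
  freq <- colMeans(g$dosage) / 2
  expect_true(all(freq > 0.05 & freq < 0.37))  # sampling noise around (0.1, 0.3)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_individuals = 0), class = "pgsmed_config_error")
  expect_error(sim_config(n_causal = 50, n_variants = 10), class = "pgsmed_config_error")
  expect_error(sim_config(within_block_r = 1), class = "pgsmed_config_error")
  expect_error(sim_config(maf_range = c(0.5, 0.1)), class = "pgsmed_config_error")
  expect_error(sim_config(missing_rate = 1), class = "pgsmed_config_error")
  expect_error(sim_config(n_discovery = -5), class = "pgsmed_config_error")
})

test_that("discovery effect estimates converge to the causal effects as n grows", {
  st <- tiny_study(n = 200, m = 50, n_causal = 10, seed = 5)
  ss <- simulate_discovery_sumstats(st$genotypes, st$true_model,
                                    n_discovery = 1e9, seed = 6)
  expect_lt(max(abs(ss$beta - st$true_model$causal_betas)), 1e-3)
})

test_that("null-variant p-values are uniform", {
  cfg <- sim_config(n_individuals = 30, n_variants = 10000, n_causal = 0,
                    ld_block_size = 1, within_block_r = 0, seed = 7)
  g <- simulate_genotypes(cfg)
  tm <- simulate_true_model(g, cfg)
  ss <- simulate_discovery_sumstats(g, tm, n_discovery = 50000, seed = 8)
  ks <- suppressWarnings(stats::ks.test(ss$p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("requested fraction of variants is rendered strand-ambiguous", {
  st <- tiny_study(n = 50, m = 100, n_causal = 5, seed = 9)
  ss <- simulate_discovery_sumstats(st$genotypes, st$true_model,
                                    n_discovery = 1e5, seed = 10,
                                    ambiguous_fraction = 0.2)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  amb <- ss$other_allele == unname(comp[ss$effect_allele])
  expect_equal(sum(amb), 20L)
})

test_that("cohort prevalence calibration hits its targets", {
  cfg <- sim_config(n_individuals = 10000, n_variants = 150, n_causal = 30,
                    prevalence_targets = c(fasting14 = 0.065), seed = 12)
  st <- simulate_study(cfg, mar = FALSE)
  prev <- mean(st$cohort$fasting14)
  expect_gte(prev, 0.052)
  expect_lte(prev, 0.078)
})

test_that("zBMI is standardized within sex and correlated with the score as designed", {
  cfg <- sim_config(n_individuals = 10000, n_variants = 150, n_causal = 30,
                    a_path = 0.35, seed = 13)
  st <- simulate_study(cfg, mar = FALSE)
  co <- st$cohort
  for (s in 0:1) {
    expect_lt(abs(mean(co$zbmi11[co$sex == s])), 0.05)
    expect_gte(sd(co$zbmi11[co$sex == s]), 0.95)
    expect_lte(sd(co$zbmi11[co$sex == s]), 1.05)
  }
  expected_r <- 0.35 / sqrt(0.35^2 + 1)
  expect_lt(abs(cor(co$true_score, co$zbmi11) - expected_r), 0.03)
})

test_that("cohort is deterministic under the same config", {
  cfg <- sim_config(n_individuals = 300, n_variants = 60, n_causal = 10, seed = 14)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$cohort, st2$cohort)
  expect_identical(st1$sumstats, st2$sumstats)
})

test_that("binary outcomes equal the dichotomized frequency items", {
  st <- tiny_study(n = 2000, m = 60, n_causal = 10, seed = 15)
  co <- st$cohort
  expect_identical(co$fasting14,
                   dichotomize_frequency(co$fasting14_freq))
  expect_identical(co$binge14,
                   dichotomize_frequency(co$binge14_freq, co$binge14_loc))
})

test_that("dichotomize_frequency implements the once-a-month rule", {
  expect_identical(dichotomize_frequency("Never"), 0L)
  expect_identical(dichotomize_frequency("Less than once a month"), 0L)
  expect_identical(dichotomize_frequency("1-3 times a month"), 1L)
  expect_identical(dichotomize_frequency("2 or more times a week"), 1L)
  # binge requires loss of control on top of monthly overeating
  expect_identical(dichotomize_frequency("Once a week", loss_of_control = 0), 0L)
  expect_identical(dichotomize_frequency("Once a week", loss_of_control = 1), 1L)
  expect_identical(dichotomize_frequency(NA_character_), NA_integer_)
  expect_error(dichotomize_frequency("sometimes"), class = "pgsmed_validation_error")
})

test_that("MAR missingness has the configured rate and direction", {
  st <- tiny_study(n = 10000, m = 60, n_causal = 10, seed = 16)
  co <- apply_mar_missingness(st$cohort, 0.3, seed = 17)
  rate <- mean(is.na(co$fasting14))
  expect_gte(rate, 0.28)
  expect_lte(rate, 0.32)

  co2 <- apply_mar_missingness(st$cohort, 0.3, delta_score = 0.5, seed = 18)
  expect_gt(mean(co2$true_score[is.na(co2$fasting14)]),
            mean(co2$true_score[!is.na(co2$fasting14)]))

  expect_identical(apply_mar_missingness(st$cohort, 0), st$cohort)
  expect_error(apply_mar_missingness(st$cohort, 1.2), class = "pgsmed_config_error")
  expect_identical(apply_mar_missingness(st$cohort, 0.3, seed = 19),
                   apply_mar_missingness(st$cohort, 0.3, seed = 19))
})

test_that("complete-case analysis adjusting for the MAR drivers is unbiased", {
  cfg <- sim_config(n_individuals = 10000, n_variants = 150, n_causal = 30, seed = 20)
  st <- simulate_study(cfg, mar = FALSE)
  co <- st$cohort
  full <- glm(fasting14 ~ true_score + zbmi11 + sex, data = co, family = binomial())
  mar <- apply_mar_missingness(co, 0.3, delta_sex = -0.5, delta_score = 0.4, seed = 21)
  cca <- glm(fasting14 ~ true_score + zbmi11 + sex, data = mar, family = binomial())
  expect_lt(abs(coef(full)["true_score"] - coef(cca)["true_score"]), 0.05)
})
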