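# pseudo-R2, liability conversion, FDR, threshold scan, permutation p

test_that("Nagelkerke R2 matches its closed form on a small fit", {
  set.seed(50)
  d <- data.frame(y = c(0, 0, 1, 0, 1, 1, 0, 1), x = c(0.1, -1, 2, 0, 1.5, 2.2, -0.5, 0.7))
  full <- suppressWarnings(glm(y ~ x, data = d, family = binomial()))
  null <- glm(y ~ 1, data = d, family = binomial())
  ll1 <- as.numeric(logLik(full))
  ll0 <- as.numeric(logLik(null))
  direct <- (1 - exp(2 / 8 * (ll0 - ll1))) / (1 - exp(2 / 8 * ll0))
  expect_equal(nagelkerke_r2(ll0, ll1, 8), direct, tolerance = 1e-10)

  expect_equal(nagelkerke_r2(ll0, ll0, 8), 0)
  # a perfectly separating predictor drives the full log-likelihood to 0
  expect_equal(nagelkerke_r2(ll0, 0, 8), 1)
  expect_error(nagelkerke_r2(ll0, ll0 - 1, 8), class = "pgsmed_domain_error")
})

test_that("liability conversion has the symmetric closed form and K = P reduction", {
  expect_equal(liability_r2(1, 0.5, 0.5), pi / 2, tolerance = 1e-6)
  expect_equal(liability_r2(0, 0.3, 0.1), 0)
  for (K in c(0.01, 0.05, 0.2)) {
    z <- dnorm(qnorm(1 - K))
    expect_equal(liability_r2(0.1, K, K), 0.1 * K * (1 - K) / z^2,
                 tolerance = 1e-12)
  }
  expect_error(liability_r2(0.1, 0), class = "pgsmed_config_error")
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(rep(1, 3)), rep(1, 3))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), class = "pgsmed_domain_error")
})

test_that("a one-point grid returns that threshold and composes with direct scoring", {
  st <- tiny_study(n = 600, m = 60, seed = 51)
  pan <- tiny_panel(st)
  pan_c <- apply_clump(pan, clump(pan, st$genotypes))

  sc <- pgs_threshold_scan(pan_c, st$genotypes, st$cohort, "fasting14",
                           grid = 0.3)
  expect_equal(sc$best_threshold, 0.3)

  # manual recomputation of the incremental Nagelkerke at the same threshold
  s <- score_pgs(pan_c, st$genotypes, 0.3)
  d <- st$cohort
  d$scorev <- s$std_score
  cc <- complete.cases(d[c("fasting14", "sex", paste0("pc", 1:4))])
  d <- d[cc, ]
  d$scorev <- (d$scorev - mean(d$scorev)) / sd(d$scorev)
  f1 <- glm(fasting14 ~ scorev + sex + pc1 + pc2 + pc3 + pc4, data = d,
            family = binomial())
  f0 <- glm(fasting14 ~ sex + pc1 + pc2 + pc3 + pc4, data = d, family = binomial())
  fi <- glm(fasting14 ~ 1, data = d, family = binomial())
  manual <- nagelkerke_r2(as.numeric(logLik(fi)), as.numeric(logLik(f1)), nrow(d)) -
    nagelkerke_r2(as.numeric(logLik(fi)), as.numeric(logLik(f0)), nrow(d))
  expect_equal(sc$best_r2_obs, manual, tolerance = 1e-8)
})

test_that("n_snps is non-decreasing along the grid and null R2 is small", {
  st <- tiny_study(n = 5000, m = 100, n_causal = 0, seed = 52,
                   c_prime = 0, b_path = 0)
  pan <- tiny_panel(st)
  pan_c <- apply_clump(pan, clump(pan, st$genotypes))
  sc <- pgs_threshold_scan(pan_c, st$genotypes, st$cohort, "fasting16",
                           grid = c(1e-4, 1e-3, 0.01, 0.1, 0.5, 1))
  expect_true(all(diff(sc$grid$n_snps) >= 0))
  expect_lt(sc$best_r2_obs, 0.005)
})

test_that("a concentrated signal is diluted at looser thresholds", {
  set.seed(53)
  n <- 2000
  causal <- rbinom(n, 2, 0.3)
  noise <- replicate(30, rbinom(n, 2, 0.3))
  dos <- cbind(causal, noise)
  colnames(dos) <- sprintf("v%03d", 1:31)
  g <- geno_from_matrix(dos)
  pan <- panel_from(g, beta = c(1, rnorm(30, 0, 0.02)),
                    p = c(1e-10, runif(30, 0.2, 1)))
  y <- rbinom(n, 1, plogis(-2 + 1.2 * scale(causal)))
  d <- tibble::tibble(id = g$samples, y = y, sex = rbinom(n, 1, 0.5),
                      pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n))
  sc <- pgs_threshold_scan(pan, g, d, "y", grid = c(1e-9, 1))
  r2_tight <- sc$grid$r2_obs[sc$grid$threshold == 1e-9]
  r2_loose <- sc$grid$r2_obs[sc$grid$threshold == 1]
  expect_gte(r2_tight, r2_loose - 0.01)
  expect_equal(sc$best_threshold, 1e-9)
})

test_that("permutation p hits the formula floor and is deterministic", {
  set.seed(54)
  n <- 500
  causal <- rbinom(n, 2, 0.4)
  dos <- cbind(causal, replicate(5, rbinom(n, 2, 0.4)))
  colnames(dos) <- sprintf("v%03d", 1:6)
  g <- geno_from_matrix(dos)
  pan <- panel_from(g, beta = c(1, rnorm(5, 0, 0.01)),
                    p = c(1e-8, runif(5, 0.1, 1)))
  y <- rbinom(n, 1, plogis(-1 + 2 * scale(causal)))  # overwhelming signal
  d <- tibble::tibble(id = g$samples, y = y, sex = rbinom(n, 1, 0.5),
                      pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n))
  r1 <- permutation_empirical_p(pan, g, d, "y", grid = c(1e-9, 0.5, 1),
                                n_perm = 99, seed = 9)
  expect_equal(r1$empirical_p, 1 / 100)
  r2 <- permutation_empirical_p(pan, g, d, "y", grid = c(1e-9, 0.5, 1),
                                n_perm = 99, seed = 9)
  expect_identical(r1$empirical_p, r2$empirical_p)
  expect_identical(r1$perm_best_p, r2$perm_best_p)
  expect_error(permutation_empirical_p(pan, g, d, "y", n_perm = 0),
               class = "pgsmed_config_error")
})

test_that("scan handles continuous outcomes with incremental R squared", {
  st <- tiny_study(n = 800, m = 60, seed = 55)
  pan <- tiny_panel(st)
  pan_c <- apply_clump(pan, clump(pan, st$genotypes))
  sc <- pgs_threshold_scan(pan_c, st$genotypes, st$cohort, "body_dissat14",
                           grid = c(0.01, 0.5, 1))
  expect_equal(sc$family, "gaussian")
  expect_true(is.na(sc$best_r2_liab))
  expect_gte(min(sc$grid$r2_obs), 0)

  g <- glance(sc)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$outcome, "body_dissat14")
  t <- tidy(sc)
  expect_equal(nrow(t), 3)
  expect_s3_class(autoplot(sc), "ggplot")
})

test_that("degenerate outcomes are rejected", {
  st <- tiny_study(n = 100, m = 20, seed = 56)
  pan <- tiny_panel(st)
  co <- st$cohort
  co$constant <- 1
  expect_error(pgs_threshold_scan(pan, st$genotypes, co, "constant", grid = 1),
               class = "pgsmed_degenerate_error")
})
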