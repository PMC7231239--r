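# counterfactual mediation: decomposition, null behavior, confounding
# sensitivity, reporting

make_mediation_data <- function(n, a = 0.5, b = 0.4, cp = 0.2,
                                family = "gaussian", alpha_y = -2.5,
                                seed = 1) {
  set.seed(seed)
  s <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  pcs <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("pc", 1:4)))
  m <- a * s + 0.2 * sex + rnorm(n)
  eta <- cp * s + b * m + 0.3 * sex
  y <- if (family == "binomial") rbinom(n, 1, plogis(alpha_y + eta)) else eta + rnorm(n)
  tibble::tibble(std_score = s, sex = sex, zbmi11 = m, y = y,
                 pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3], pc4 = pcs[, 4])
}

test_that("estimates are deterministic under a fixed seed", {
  d <- make_mediation_data(800, seed = 80)
  f1 <- estimate_mediation(d, "y", n_resamples = 150, seed = 5)
  f2 <- estimate_mediation(d, "y", n_resamples = 150, seed = 5)
  expect_identical(f1$estimates, f2$estimates)
  f3 <- estimate_mediation(d, "y", n_resamples = 150, seed = 6)
  expect_false(identical(f1$estimates$conf.low, f3$estimates$conf.low))
})

test_that("the averaged decomposition is exactly additive", {
  d <- make_mediation_data(1500, family = "binomial", seed = 81)
  f <- estimate_mediation(d, "y", n_resamples = 150, seed = 2)
  e <- f$estimates
  expect_equal(e$estimate[e$term == "total"],
               e$estimate[e$term == "ade"] + e$estimate[e$term == "acme"],
               tolerance = 1e-12)
  # additivity also holds within every resample
  expect_equal(f$draws[, "total"], f$draws[, "ade"] + f$draws[, "acme"],
               tolerance = 1e-12)
})

test_that("the linear case approaches the product-of-coefficients values", {
  d <- make_mediation_data(4000, a = 0.5, b = 0.4, cp = 0.2, seed = 82)
  f <- estimate_mediation(d, "y", n_resamples = 200,
                          inference = "quasi-bayesian", seed = 3)
  e <- f$estimates
  expect_lt(abs(e$estimate[e$term == "acme"] - 0.5 * 0.4), 0.04)
  expect_lt(abs(e$estimate[e$term == "ade"] - 0.2), 0.04)
})

test_that("with no mediator-outcome path the ACME is null and covered", {
  covered <- 0L
  acmes <- numeric(40)
  for (r in seq_len(40)) {
    d <- make_mediation_data(2500, a = 0.5, b = 0, cp = 0.3,
                             family = "binomial", seed = 100 + r)
    f <- estimate_mediation(d, "y", n_resamples = 150,
                            inference = "quasi-bayesian", seed = r)
    e <- f$estimates
    acmes[r] <- e$estimate[e$term == "acme"]
    if (e$conf.low[e$term == "acme"] <= 0 && e$conf.high[e$term == "acme"] >= 0) {
      covered <- covered + 1L
    }
  }
  expect_lt(mean(abs(acmes)), 0.01)
  expect_gte(covered, 33)  # ~95% nominal coverage, allowing sampling slack
})

test_that("an unmeasured mediator-outcome confounder biases the ACME upward", {
  set.seed(83)
  n <- 6000
  s <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  u <- rnorm(n)                      # confounder of mediator and outcome
  m <- 0.4 * s + 0.6 * u + rnorm(n)
  y <- 0.2 * s + 0 * m + 0.6 * u + rnorm(n)  # no true mediated path
  d <- tibble::tibble(std_score = s, sex = sex, zbmi11 = m, y = y, u = u)

  f_unadj <- estimate_mediation(d, "y", covariates = "sex",
                                n_resamples = 150, inference = "quasi-bayesian",
                                seed = 1)
  f_adj <- estimate_mediation(d, "y", covariates = c("sex", "u"),
                              n_resamples = 150, inference = "quasi-bayesian",
                              seed = 1)
  acme_unadj <- f_unadj$estimates$estimate[f_unadj$estimates$term == "acme"]
  acme_adj <- f_adj$estimates$estimate[f_adj$estimates$term == "acme"]
  expect_gt(acme_unadj, acme_adj + 0.05)  # omitted confounding inflates ACME
  expect_lt(abs(acme_adj), 0.03)
})

test_that("bootstrap and quasi-Bayesian inference agree on the point estimates", {
  d <- make_mediation_data(2000, family = "binomial", seed = 84)
  fb <- estimate_mediation(d, "y", n_resamples = 150, seed = 4)
  fq <- estimate_mediation(d, "y", n_resamples = 150,
                           inference = "quasi-bayesian", seed = 4)
  expect_equal(fb$estimates$estimate, fq$estimates$estimate, tolerance = 1e-6)
  expect_lt(max(abs(fb$estimates$conf.low - fq$estimates$conf.low)), 0.05)
})

test_that("the report table mirrors the decomposition and handles empty input", {
  d <- make_mediation_data(1200, family = "binomial", seed = 85)
  f <- estimate_mediation(d, "y", n_resamples = 150, seed = 7)
  rep1 <- mediation_report(list(fasting14 = f))
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$phenotype, "fasting")
  expect_equal(rep1$age, 14)
  expect_equal(rep1$total, rep1$ade + rep1$acme, tolerance = 1e-12)

  rep0 <- mediation_report(list())
  expect_equal(nrow(rep0), 0)
  expect_true(all(c("phenotype", "total", "ade_p", "acme_hi") %in% names(rep0)))
})

test_that("proportion mediated is reported only with a sign-consistent total", {
  d <- make_mediation_data(4000, a = 0.5, b = 0.5, cp = 0.3, seed = 86)
  f <- estimate_mediation(d, "y", n_resamples = 150,
                          inference = "quasi-bayesian", seed = 8)
  expect_false(is.na(f$prop_mediated))
  expect_gt(f$prop_mediated, 0)

  d0 <- make_mediation_data(600, a = 0, b = 0, cp = 0, seed = 87)
  f0 <- estimate_mediation(d0, "y", n_resamples = 150,
                           inference = "quasi-bayesian", seed = 9)
  expect_true(is.na(f0$prop_mediated))
})

test_that("tidiers and the plot method expose the fit", {
  d <- make_mediation_data(900, family = "binomial", seed = 88)
  f <- estimate_mediation(d, "y", n_resamples = 120, seed = 10)
  expect_equal(tidy(f)$term, c("total", "ade", "acme"))
  expect_equal(glance(f)$n, nrow(d))
  expect_s3_class(autoplot(f), "ggplot")
  expect_error(estimate_mediation(d, "y", n_resamples = 50),
               class = "pgsmed_config_error")
})
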