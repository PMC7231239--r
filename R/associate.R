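# Final covariate-adjusted association estimates: odds ratios / standardized
# betas per 1 SD of the score, sex interaction and stratified fits, FDR
# across phenotypes.

#' Covariate-adjusted association of an outcome with the standardized score
#'
#' Fits `outcome ~ score + covariates` by maximum likelihood (logistic, 0/1
#' outcomes) or least squares (linear) on complete cases. Binary effects are
#' odds ratios per 1 SD of the standardized score with Wald 95% CIs on the
#' log scale; continuous effects are betas per 1 SD of the score on the raw
#' outcome scale. Incremental R-squared (and its liability-scale version for
#' binary outcomes, `K` = sample case fraction unless given) is included.
#'
#' @param data Cohort tibble containing the outcome, score and covariates.
#' @param outcome Outcome column name.
#' @param score Score column name (should be standardized).
#' @param covariates Covariate column names.
#' @param family `"binomial"`, `"gaussian"`, or `NULL` to infer.
#' @param prevalence_k Optional population prevalence for the liability
#'   conversion.
#' @return An `assoc_result`: one-row tibble with outcome, family, n,
#'   n_cases, n_controls, estimate (OR or beta), conf.low, conf.high,
#'   p.value, r2_obs, r2_liab.
#' @export
fit_association <- function(data, outcome, score = "std_score",
                            covariates = c("sex", paste0("pc", 1:4)),
                            family = NULL, prevalence_k = NULL) {
  cc <- complete.cases(data[c(outcome, score, covariates)])
  d <- data[cc, ]
  y <- d[[outcome]]
  if (length(unique(y)) < 2) {
    abort(sprintf("outcome `%s` is constant on complete cases", outcome),
          class = "pgsmed_degenerate_error")
  }
  if (is.null(family)) family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"

  rhs <- paste(c(score, covariates), collapse = " + ")
  f_full <- as.formula(paste(outcome, "~", rhs))
  f_cov <- as.formula(paste(outcome, "~",
                            if (length(covariates)) paste(covariates, collapse = " + ") else "1"))

  if (family == "binomial") {
    fit <- glm(f_full, data = d, family = binomial())
    if (!fit$converged || any(abs(coef(fit)) > 15)) {
      abort(sprintf("logistic fit for `%s` did not converge (separation?)", outcome),
            class = "pgsmed_separation_error")
    }
    fit0 <- glm(f_cov, data = d, family = binomial())
    fit00 <- glm(as.formula(paste(outcome, "~ 1")), data = d, family = binomial())
    b <- coef(fit)[score]
    se <- sqrt(vcov(fit)[score, score])
    r2 <- nagelkerke_r2(as.numeric(logLik(fit00)), as.numeric(logLik(fit)), nrow(d)) -
      nagelkerke_r2(as.numeric(logLik(fit00)), as.numeric(logLik(fit0)), nrow(d))
    P <- mean(y)
    K <- prevalence_k %||% P
    res <- tibble(
      outcome = outcome, family = family, n = nrow(d),
      n_cases = sum(y == 1), n_controls = sum(y == 0),
      estimate = exp(unname(b)),
      conf.low = exp(unname(b) - qnorm(0.975) * unname(se)),
      conf.high = exp(unname(b) + qnorm(0.975) * unname(se)),
      p.value = unname(2 * pnorm(-abs(b / se))),
      r2_obs = r2, r2_liab = liability_r2(r2, K, P)
    )
  } else {
    fit <- lm(f_full, data = d)
    fit0 <- lm(f_cov, data = d)
    b <- coef(fit)[score]
    se <- sqrt(vcov(fit)[score, score])
    df <- fit$df.residual
    r2 <- summary(fit)$r.squared - summary(fit0)$r.squared
    res <- tibble(
      outcome = outcome, family = family, n = nrow(d),
      n_cases = NA_integer_, n_controls = NA_integer_,
      estimate = unname(b),
      conf.low = unname(b - qt_(0.975, df) * se),
      conf.high = unname(b + qt_(0.975, df) * se),
      p.value = unname(2 * pt(-abs(b / se), df)),
      r2_obs = r2, r2_liab = NA_real_
    )
  }
  structure(res, class = c("assoc_result", class(tibble())))
}

qt_ <- function(p, df) stats::qt(p, df)

#' Score-by-sex interaction and sex-stratified fits
#'
#' Adds a `score x sex` product term to the association model and reports the
#' Wald p-value for it, together with the two sex-stratified fits.
#'
#' @inheritParams fit_association
#' @return List with `interaction_p`, `interaction_estimate`, and
#'   `stratified` (an `assoc_result` per sex, with a `sex` column).
#' @export
sex_interaction <- function(data, outcome, score = "std_score",
                            covariates = c(paste0("pc", 1:4)),
                            family = NULL) {
  cc <- complete.cases(data[c(outcome, score, "sex", covariates)])
  d <- data[cc, ]
  if (length(unique(d$sex)) < 2) {
    abort("both sexes must be present for the interaction model",
          class = "pgsmed_stratification_error")
  }
  y <- d[[outcome]]
  if (is.null(family)) family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"

  rhs <- paste(c(sprintf("%s * sex", score), covariates), collapse = " + ")
  f <- as.formula(paste(outcome, "~", rhs))
  fit <- if (family == "binomial") glm(f, data = d, family = binomial()) else lm(f, data = d)
  term <- paste0(score, ":sex")
  b <- coef(fit)[term]
  se <- sqrt(vcov(fit)[term, term])

  strat <- dplyr::bind_rows(lapply(sort(unique(d$sex)), function(s) {
    r <- fit_association(d[d$sex == s, ], outcome, score, covariates, family)
    r$sex <- s
    r
  }))

  list(
    interaction_estimate = unname(b),
    interaction_se = unname(se),
    interaction_p = unname(2 * pnorm(-abs(b / se))),
    stratified = strat
  )
}

#' FDR adjustment across a family of phenotype tests
#'
#' Applies Benjamini-Hochberg across the supplied association results,
#' adding a `q` column.
#'
#' @param results A tibble of stacked `assoc_result` rows (>= 1 row).
#' @return The same tibble with `q`.
#' @export
fdr_across_phenotypes <- function(results) {
  stopifnot(nrow(results) >= 1, "p.value" %in% names(results))
  results$q <- bh_fdr(results$p.value)
  results
}
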