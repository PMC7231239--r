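# Counterfactual causal mediation: total effect, average direct effect (ADE)
# and average causal mediation effect (ACME) of a 1-SD score contrast on an
# outcome through the zBMI mediator, with resampling inference.
#
# Identification assumes sequential ignorability (no unmeasured
# treatment-outcome, treatment-mediator or mediator-outcome confounding given
# the covariates, and no intermediate confounders).

#' Estimate natural direct and indirect effects
#'
#' Algorithm: (1) fit the mediator model `M ~ treatment + covariates` by
#' least squares; (2) fit the outcome model `Y ~ treatment + mediator +
#' covariates` (logistic for 0/1 outcomes, else linear; no
#' treatment-mediator interaction); (3) for every observed covariate profile
#' draw potential mediators `M(t0)`, `M(t1)` from the fitted mediator model
#' (common residual draw across treatment levels), evaluate the
#' model-implied outcome (probability for binary outcomes) at all four
#' `(t, t')` combinations, and average:
#' `ACME(t) = mean[Y(t, M(t1)) - Y(t, M(t0))]`,
#' `ADE(t) = mean[Y(t1, M(t)) - Y(t0, M(t))]`; the reported ACME/ADE average
#' the two treatment arms and the total effect is their sum (the averaged
#' decomposition is exact). (4) Inference by nonparametric bootstrap
#' (refitting both models per resample; default) or quasi-Bayesian draws of
#' the coefficients from their asymptotic normal, with percentile 95% CIs
#' and two-sided resampling p-values.
#'
#' Effects are risk differences (binary) or mean differences (continuous)
#' per `t1 - t0` change in the treatment — by default a 1 SD contrast (0 to
#' 1) of the standardized score.
#'
#' @param data Cohort tibble.
#' @param outcome,mediator,treatment,covariates Column names.
#' @param family Outcome family (`"binomial"`/`"gaussian"`; `NULL` infers).
#' @param n_resamples Bootstrap/quasi-Bayesian resamples (>= 100).
#' @param inference `"bootstrap"` (default) or `"quasi-bayesian"`.
#' @param t0,t1 Treatment contrast levels (default 0 and 1).
#' @param mediator_draws Potential-mediator residual draws per resample.
#' @param seed Integer seed.
#' @return A `mediation_fit`: estimates for total effect, ADE, ACME with CIs
#'   and p-values, proportion mediated (reported only when the total effect's
#'   sign is consistent across >= 95% of resamples), and the resample draws.
#' @export
estimate_mediation <- function(data, outcome, mediator = "zbmi11",
                               treatment = "std_score",
                               covariates = c("sex", paste0("pc", 1:4)),
                               family = NULL, n_resamples = 1000,
                               inference = c("bootstrap", "quasi-bayesian"),
                               t0 = 0, t1 = 1, mediator_draws = 1,
                               seed = 1L) {
  inference <- match.arg(inference)
  n_resamples <- check_count(n_resamples, "n_resamples", min = 100)
  if (abs((t1 - t0) - 1) > 1e-12) {
    warn("treatment contrast is not 1 SD; effects are per (t1 - t0) units",
         class = "pgsmed_qc_warning")
  }

  cols <- c(outcome, mediator, treatment, covariates)
  d <- data[complete.cases(data[cols]), cols]
  n <- nrow(d)
  if (n == 0) abort("no complete-case rows", class = "pgsmed_input_error")
  y <- d[[outcome]]
  if (is.null(family)) family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"

  M <- d[[mediator]]
  Tr <- d[[treatment]]
  C <- as.matrix(d[covariates])

  Xm <- cbind(1, Tr, C)
  Xy <- cbind(1, Tr, M, C)

  # point estimate from the full-sample fits; many residual draws to make the
  # plug-in estimate nearly deterministic
  theta_hat <- fit_mediation_models(Xm, M, Xy, y, family)
  if (!theta_hat$converged) {
    abort("outcome model did not converge on the full sample",
          class = "pgsmed_inference_error")
  }
  point <- with_substream(seed, "mediation-point", {
    mediation_effects(theta_hat, C, t0, t1, family, n_draws = 50L)
  })

  draws <- matrix(NA_real_, n_resamples, 3,
                  dimnames = list(NULL, c("total", "ade", "acme")))
  n_fail <- 0L
  with_substream(seed, "mediation-resample", {
    if (inference == "bootstrap") {
      for (r in seq_len(n_resamples)) {
        idx <- sample.int(n, n, replace = TRUE)
        th <- fit_mediation_models(Xm[idx, , drop = FALSE], M[idx],
                                   Xy[idx, , drop = FALSE], y[idx], family)
        if (!th$converged) {
          n_fail <- n_fail + 1L
          next
        }
        draws[r, ] <- mediation_effects(th, C, t0, t1, family, mediator_draws)
      }
    } else {
      qb <- quasi_bayes_setup(d, outcome, mediator, treatment, covariates, family)
      for (r in seq_len(n_resamples)) {
        th <- quasi_bayes_draw(qb)
        draws[r, ] <- mediation_effects(th, C, t0, t1, family, mediator_draws)
      }
    }
  })
  if (n_fail > 0.05 * n_resamples) {
    abort(sprintf("outcome model failed to converge in %d of %d resamples",
                  n_fail, n_resamples), class = "pgsmed_inference_error")
  }
  draws <- draws[!is.na(draws[, 1]), , drop = FALSE]

  est <- tibble(
    term = c("total", "ade", "acme"),
    estimate = as.numeric(point),
    conf.low = apply(draws, 2, quantile, 0.025),
    conf.high = apply(draws, 2, quantile, 0.975),
    p.value = apply(draws, 2, resample_p)
  )

  sign_consistent <- mean(sign(draws[, "total"]) == sign(point[["total"]])) >= 0.95
  structure(
    list(
      estimates = est,
      prop_mediated = if (sign_consistent) unname(point[["acme"]] / point[["total"]]) else NA_real_,
      draws = draws,
      outcome = outcome, mediator = mediator, treatment = treatment,
      family = family, n = n, n_resamples = n_resamples,
      n_failed = n_fail, inference = inference, t0 = t0, t1 = t1,
      seed = seed
    ),
    class = "mediation_fit"
  )
}

# two-sided resampling p-value with add-one smoothing
resample_p <- function(x) {
  R <- length(x)
  min(1, 2 * min((1 + sum(x <= 0)) / (R + 1), (1 + sum(x >= 0)) / (R + 1)))
}

fit_mediation_models <- function(Xm, M, Xy, y, family) {
  fm <- .fast_ols(Xm, M)
  sigma_m <- sqrt(fm$rss / (length(M) - ncol(Xm)))
  if (family == "binomial") {
    fy <- .fast_logistic(Xy, y)
    conv <- isTRUE(fy$converged) && all(is.finite(fy$coef)) &&
      all(abs(fy$coef) < 30)
    list(coef_m = as.numeric(fm$coef), sigma_m = sigma_m,
         coef_y = as.numeric(fy$coef), converged = conv)
  } else {
    fy <- .fast_ols(Xy, y)
    list(coef_m = as.numeric(fm$coef), sigma_m = sigma_m,
         coef_y = as.numeric(fy$coef), converged = all(is.finite(fy$coef)))
  }
}

# potential-outcome averaging over the observed covariate profiles
# coef_m = (intercept, a, gamma_m...), coef_y = (intercept, c', b, gamma_y...)
mediation_effects <- function(theta, C, t0, t1, family, n_draws = 1L) {
  n <- nrow(C)
  a <- theta$coef_m[2]
  base_m <- theta$coef_m[1] + C %*% theta$coef_m[-(1:2)]
  cp <- theta$coef_y[2]
  b <- theta$coef_y[3]
  base_y <- theta$coef_y[1] + C %*% theta$coef_y[-(1:3)]
  link <- if (family == "binomial") plogis else identity

  acme0 <- acme1 <- ade0 <- ade1 <- 0
  for (dr in seq_len(n_draws)) {
    eps <- rnorm(n, 0, theta$sigma_m)  # common draw across treatment levels
    m0 <- base_m + a * t0 + eps
    m1 <- base_m + a * t1 + eps
    y_t0_m0 <- link(base_y + cp * t0 + b * m0)
    y_t0_m1 <- link(base_y + cp * t0 + b * m1)
    y_t1_m0 <- link(base_y + cp * t1 + b * m0)
    y_t1_m1 <- link(base_y + cp * t1 + b * m1)
    acme0 <- acme0 + mean(y_t0_m1 - y_t0_m0)
    acme1 <- acme1 + mean(y_t1_m1 - y_t1_m0)
    ade0 <- ade0 + mean(y_t1_m0 - y_t0_m0)
    ade1 <- ade1 + mean(y_t1_m1 - y_t0_m1)
  }
  acme <- (acme0 + acme1) / (2 * n_draws)
  ade <- (ade0 + ade1) / (2 * n_draws)
  c(total = acme + ade, ade = ade, acme = acme)
}

quasi_bayes_setup <- function(d, outcome, mediator, treatment, covariates,
                              family) {
  fm <- lm(as.formula(paste(mediator, "~", paste(c(treatment, covariates),
                                                 collapse = " + "))), data = d)
  fy_formula <- as.formula(paste(outcome, "~", paste(c(treatment, mediator, covariates),
                                                     collapse = " + ")))
  fy <- if (family == "binomial") {
    glm(fy_formula, data = d, family = binomial())
  } else {
    lm(fy_formula, data = d)
  }
  list(
    mean_m = coef(fm), chol_m = chol(vcov(fm)), sigma_m = summary(fm)$sigma,
    mean_y = coef(fy), chol_y = chol(vcov(fy))
  )
}

quasi_bayes_draw <- function(qb) {
  cm <- qb$mean_m + drop(rnorm(length(qb$mean_m)) %*% qb$chol_m)
  cy <- qb$mean_y + drop(rnorm(length(qb$mean_y)) %*% qb$chol_y)
  list(coef_m = as.numeric(cm), sigma_m = qb$sigma_m,
       coef_y = as.numeric(cy), converged = TRUE)
}

#' @method print mediation_fit
#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("<mediation_fit> %s ~ %s via %s (%s), n = %d, %s x %d\n",
              x$outcome, x$treatment, x$mediator, x$family, x$n,
              x$inference, x$n_resamples))
  e <- x$estimates
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-6s %8.4f  [%.4f, %.4f]  p = %.4g\n", e$term[i],
                e$estimate[i], e$conf.low[i], e$conf.high[i], e$p.value[i]))
  }
  if (!is.na(x$prop_mediated)) {
    cat(sprintf("  proportion mediated = %.3f\n", x$prop_mediated))
  }
  invisible(x)
}

#' Assemble a mediation results table
#'
#' One row per fitted outcome with the total effect, average direct effect
#' and average causal mediation effect (each with its 95% CI and resampling
#' p-value). The total column is recomputed as `ade + acme`, which the
#' averaged decomposition satisfies exactly.
#'
#' @param results A list of `mediation_fit` objects (possibly named;
#'   names become phenotype labels).
#' @return A tibble: phenotype, age, n, total/ade/acme estimate, CI bounds
#'   and p-value columns. Empty input gives a zero-row table with the same
#'   columns.
#' @export
mediation_report <- function(results) {
  cols <- c("phenotype", "age", "n",
             "total", "total_lo", "total_hi", "total_p",
             "ade", "ade_lo", "ade_hi", "ade_p",
             "acme", "acme_lo", "acme_hi", "acme_p")
  if (length(results) == 0) {
    out <- tibble::as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$phenotype <- character(0)
    return(out[cols])
  }
  rows <- purrr::imap(results, function(fit, nm) {
    stopifnot(inherits(fit, "mediation_fit"))
    e <- fit$estimates
    g <- function(term, col) e[[col]][e$term == term]
    label <- if (is.character(nm) && nzchar(nm)) nm else fit$outcome
    age <- suppressWarnings(as.numeric(sub("^\\D*", "", label)))
    tibble(
      phenotype = sub("[0-9]+$", "", label), age = age, n = fit$n,
      total = g("ade", "estimate") + g("acme", "estimate"),
      total_lo = g("total", "conf.low"), total_hi = g("total", "conf.high"),
      total_p = g("total", "p.value"),
      ade = g("ade", "estimate"), ade_lo = g("ade", "conf.low"),
      ade_hi = g("ade", "conf.high"), ade_p = g("ade", "p.value"),
      acme = g("acme", "estimate"), acme_lo = g("acme", "conf.low"),
      acme_hi = g("acme", "conf.high"), acme_p = g("acme", "p.value")
    )
  })
  dplyr::bind_rows(rows)
}
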