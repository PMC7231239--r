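# broom-style tidy()/glance() methods for the package's fitted objects

#' Tidy a threshold scan
#'
#' @param x A `pgs_scan`.
#' @param ... Unused.
#' @return Per-threshold tibble: threshold, n_snps, r2_obs, p_model.
#' @export
tidy.pgs_scan <- function(x, ...) x$grid

#' @rdname tidy.pgs_scan
#' @return For `glance()`: one-row tibble with the best-fit summary.
#' @export
glance.pgs_scan <- function(x, ...) {
  tibble(
    outcome = x$outcome, family = x$family, n = x$n,
    best_threshold = x$best_threshold, n_snps = x$best_n_snps,
    r2_obs = x$best_r2_obs, r2_liab = x$best_r2_liab,
    p_model = x$best_p_model,
    empirical_p = x$empirical_p %||% NA_real_,
    n_permutations = x$n_permutations %||% NA_integer_
  )
}

#' Tidy a mediation fit
#'
#' @param x A `mediation_fit`.
#' @param ... Unused.
#' @return Tibble with total/ade/acme estimates, CIs and p-values.
#' @export
tidy.mediation_fit <- function(x, ...) x$estimates

#' @rdname tidy.mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  e <- x$estimates
  tibble(
    outcome = x$outcome, mediator = x$mediator, family = x$family, n = x$n,
    total = e$estimate[e$term == "total"],
    ade = e$estimate[e$term == "ade"],
    acme = e$estimate[e$term == "acme"],
    prop_mediated = x$prop_mediated,
    n_resamples = x$n_resamples, inference = x$inference
  )
}

#' Tidy a longitudinal random-intercept fit
#'
#' @param x A `glmm_fit`.
#' @param ... Unused.
#' @return Fixed-effects tibble (per-year age scale).
#' @export
tidy.glmm_fit <- function(x, ...) x$fixed

#' @rdname tidy.glmm_fit
#' @export
glance.glmm_fit <- function(x, ...) {
  tibble(
    n_obs = x$n_obs, n_persons = x$n_persons, sigma2 = x$sigma2,
    interaction_p = x$interaction_p, logLik = x$loglik, nAGQ = x$nAGQ
  )
}
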