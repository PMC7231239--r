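# Longitudinal random-intercept logistic models: does the score-outcome
# association differ across ages 14/16/18?

#' Build the long-format outcome table
#'
#' Stacks a behavior's per-age binary outcomes (e.g. fasting14/16/18) into
#' person-age records, attaching the standardized score (conventionally at
#' threshold 1 so the same score is used at every age), sex and PCs.
#'
#' @param cohort Cohort tibble with per-age outcome columns and an `id`.
#' @param scores A `pgs_vector` (or tibble with sample_id, std_score).
#' @param behavior Behavior stem, e.g. `"fasting"`; columns `<stem><age>` are
#'   collected.
#' @param ages Ages to include (default those found).
#' @return Long tibble: id, age (years), outcome, std_score, sex, pc1-pc4.
#' @export
build_long_table <- function(cohort, scores, behavior,
                             ages = c(14, 16, 18)) {
  cols <- paste0(behavior, ages)
  cols_found <- cols[cols %in% names(cohort)]
  if (length(cols_found) < 2) {
    abort(sprintf("need >= 2 age columns for behavior `%s`", behavior),
          class = "pgsmed_input_error")
  }
  d <- dplyr::inner_join(
    cohort[c("id", "sex", paste0("pc", 1:4), cols_found)],
    tibble(id = scores$sample_id, std_score = scores$std_score),
    by = "id"
  )
  out <- tidyr::pivot_longer(d, dplyr::all_of(cols_found),
                             names_to = "age", values_to = "outcome")
  out$age <- as.numeric(sub(behavior, "", out$age, fixed = TRUE))
  out <- out[!is.na(out$outcome), c("id", "age", "outcome", "std_score",
                                    "sex", paste0("pc", 1:4))]
  out
}

#' Random-intercept logistic model with a score-by-age interaction
#'
#' Fits `logit P(y_it = 1) = b0 + u_i + b1 score_i + b2 age_t + b3 score_i x
#' age_t + covariates`, `u_i ~ N(0, sigma2)`, by adaptive Gauss-Hermite
#' quadrature ([lme4::glmer()], `nAGQ` nodes, default 9). Age is centered at
#' the first age and scaled to 2-year units for conditioning; reported
#' effects are rescaled back to per-year. On non-convergence the fit is
#' retried with more quadrature nodes.
#'
#' @param long_table Output of [build_long_table()].
#' @param covariates Additional fixed-effect columns (default sex + PCs).
#' @param nAGQ Quadrature nodes (>= 1; 1 = Laplace).
#' @param age_coding `"linear"` (default) or `"categorical"`.
#' @return A `glmm_fit`: list with the `lme4` fit, fixed-effect table
#'   (per-year scale), `sigma2`, and `interaction_p` (Wald).
#' @export
fit_glmm_interaction <- function(long_table,
                                 covariates = c("sex", paste0("pc", 1:4)),
                                 nAGQ = 9, age_coding = c("linear", "categorical")) {
  age_coding <- match.arg(age_coding)
  ages <- sort(unique(long_table$age))
  if (length(ages) < 2) {
    abort("need >= 2 distinct ages", class = "pgsmed_input_error")
  }
  d <- long_table
  d <- d[complete.cases(d[c("outcome", "std_score", covariates)]), ]
  # center at the first age, 2-year units, for better conditioning
  d$age_u <- if (age_coding == "linear") (d$age - min(ages)) / 2 else factor(d$age)

  f <- as.formula(paste(
    "outcome ~ std_score * age_u +",
    paste(covariates, collapse = " + "), "+ (1 | id)"
  ))
  fit <- NULL
  converged <- FALSE
  for (nq in unique(c(nAGQ, nAGQ + 6, 25))) {
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(f, data = d, family = binomial(), nAGQ = nq,
                  control = lme4::glmerControl(optimizer = "bobyqa",
                                               optCtrl = list(maxfun = 1e5)))
    ))
    msgs <- fit@optinfo$conv$lme4$messages %||% character(0)
    # a boundary (singular) fit is a valid solution, not a failure; a
    # max-gradient slightly above lme4's strict tolerance is accepted too
    msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
    grad_msg <- grepl("max\\|grad\\|", msgs)
    if (any(grad_msg)) {
      grads <- suppressWarnings(as.numeric(sub(".*max\\|grad\\| = ([0-9.eE+-]+).*",
                                               "\\1", msgs[grad_msg])))
      if (all(is.finite(grads)) && all(grads < 0.05)) msgs <- msgs[!grad_msg]
    }
    if (fit@optinfo$conv$opt == 0 && length(msgs) == 0) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(paste0("GLMM did not converge after quadrature-node escalation: ",
                 paste(fit@optinfo$conv$lme4$messages, collapse = "; ")),
          class = "pgsmed_convergence_error")
  }

  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  tab <- tibble(term = names(fe), estimate = unname(fe), std.error = unname(se),
                statistic = unname(fe / se),
                p.value = unname(2 * pnorm(-abs(fe / se))))
  if (age_coding == "linear") {
    # rescale the 2-year-unit age terms back to per-year
    sc <- grepl("age_u", tab$term)
    tab$estimate[sc] <- tab$estimate[sc] / 2
    tab$std.error[sc] <- tab$std.error[sc] / 2
  }
  int_term <- grep("std_score:age_u", tab$term, value = TRUE)[1]
  structure(
    list(
      fit = fit,
      fixed = tab,
      sigma2 = as.numeric(lme4::VarCorr(fit)$id[1]),
      interaction_term = int_term,
      interaction_p = tab$p.value[tab$term == int_term],
      loglik = as.numeric(logLik(fit)),
      n_obs = nrow(d), n_persons = length(unique(d$id)),
      nAGQ = fit@devcomp$dims[["nAGQ"]],
      age_coding = age_coding
    ),
    class = "glmm_fit"
  )
}

#' @method print glmm_fit
#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %d obs, %d persons, sigma2 = %.3f, nAGQ = %d\n",
              x$n_obs, x$n_persons, x$sigma2, x$nAGQ))
  cat(sprintf("  score x age interaction p = %.3g\n", x$interaction_p))
  invisible(x)
}
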