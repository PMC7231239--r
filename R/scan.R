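# High-resolution p-value-threshold optimization: incremental pseudo-R2 over
# a threshold grid, liability-scale conversion, permutation empirical
# p-values, and BH-FDR.

#' Nagelkerke pseudo-R-squared
#'
#' `[1 - exp((2/n) (ll0 - ll1))] / [1 - exp((2/n) ll0)]`, the Cox-Snell ratio
#' rescaled to a maximum of 1.
#'
#' @param loglik_null Log-likelihood of the null model.
#' @param loglik_full Log-likelihood of the full model (`>= loglik_null`).
#' @param n Number of observations.
#' @return Pseudo-R-squared in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_full, n) {
  stopifnot(n >= 1)
  if (loglik_full < loglik_null - 1e-8) {
    abort("`loglik_full` must be >= `loglik_null`.", class = "pgsmed_domain_error")
  }
  denom <- 1 - exp(2 / n * loglik_null)
  if (denom == 0) {
    abort("degenerate null likelihood: Nagelkerke R2 undefined",
          class = "pgsmed_domain_error")
  }
  (1 - exp(2 / n * (loglik_null - loglik_full))) / denom
}

#' Liability-scale conversion of an observed-scale R-squared
#'
#' Multiplies the observed-scale R-squared by
#' `K^2 (1-K)^2 / (z^2 P (1-P))`, where `K` is the population prevalence,
#' `P` the sample case fraction and `z` the standard-normal density at the
#' liability threshold `qnorm(1 - K)`. With `K = P` (a population sample)
#' the multiplier reduces to `K (1 - K) / z^2`.
#'
#' @param r2_observed Observed-scale R-squared.
#' @param prevalence_k Population prevalence `K` in `(0, 1)`.
#' @param case_fraction_p Sample case fraction `P` in `(0, 1)`; defaults to
#'   `K`.
#' @return Liability-scale R-squared.
#' @export
liability_r2 <- function(r2_observed, prevalence_k,
                         case_fraction_p = prevalence_k) {
  K <- check_prob(prevalence_k, "prevalence_k")
  P <- check_prob(case_fraction_p, "case_fraction_p")
  z <- dnorm(qnorm(1 - K))
  r2_observed * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}

#' Benjamini-Hochberg adjusted Q values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric p-values in `(0, 1]`.
#' @return Adjusted Q values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1].", class = "pgsmed_domain_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Default p-value threshold grid
#'
#' The genome-wide-significance anchors `{5e-8, 1e-6, 1e-5}` plus a dense
#' sweep from 1e-4 to 1 in steps of 1e-4 (high-resolution scoring).
#'
#' @return Sorted numeric vector of thresholds.
#' @export
default_grid <- function() {
  sort(unique(c(5e-8, 1e-6, 1e-5, seq(1e-4, 1, by = 1e-4))))
}

# Shared precomputation for scan and permutation: complete-case rows,
# covariate design matrix, and the standardized score column for every
# distinct included-variant set along the grid (thresholds between two
# consecutive ordered p-values give identical scores, so only those sets are
# fitted).
scan_context <- function(panel, genotypes, data, outcome, covariates, grid,
                         family) {
  al <- align_samples(genotypes, data)
  data <- al$cohort
  cc <- complete.cases(data[c(outcome, covariates)])
  data <- data[cc, ]
  dos <- al$genotypes$dosage[cc, , drop = FALSE]
  n <- nrow(data)
  if (n == 0) abort("no complete-case rows", class = "pgsmed_input_error")

  y <- data[[outcome]]
  if (length(unique(y)) < 2) {
    abort(sprintf("outcome `%s` is constant on complete cases", outcome),
          class = "pgsmed_degenerate_error")
  }
  if (is.null(family)) {
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  }

  X_cov <- cbind(`(Intercept)` = 1, as.matrix(data[covariates]))

  g_small <- genotype_matrix(dos, al$genotypes$variants)
  ord <- order(panel$p, panel$pos, panel$snp_id)
  panel_o <- panel[ord, ]
  contrib <- oriented_dosage(panel_o, g_small) *
    rep(panel_o$beta, each = n)

  grid <- sort(grid)
  n_snps <- findInterval(grid, panel_o$p)  # p sorted ascending within panel_o
  counts <- unique(n_snps)

  # cumulative raw scores at each distinct count, standardized per column
  S <- matrix(0, n, length(counts))
  running <- rep(0, n)
  done <- 0L
  for (u in seq_along(counts)) {
    k <- counts[u]
    if (k > done) {
      running <- running + rowSums(contrib[, (done + 1L):k, drop = FALSE])
      done <- k
    }
    S[, u] <- running
  }
  S_std <- apply(S, 2, function(s) if (sd(s) > 0) (s - mean(s)) / sd(s) else s * 0)
  S_std <- matrix(S_std, nrow = n)

  list(data = data, y = y, X_cov = X_cov, S_std = S_std, counts = counts,
       grid = grid, grid_counts = n_snps, family = family, n = n)
}

# fit every distinct score column against an outcome vector; returns
# incremental R2 and model p per column plus the covariate-only fit stats
fit_grid <- function(ctx, y) {
  n <- length(y)
  U <- ncol(ctx$S_std)
  r2 <- numeric(U)
  pval <- numeric(U)

  if (ctx$family == "binomial") {
    ll_int <- binom_loglik_intercept(y)
    f_cov <- .fast_logistic(ctx$X_cov, y)
    nk_cov <- nagelkerke_r2(ll_int, f_cov$loglik, n)
    for (u in seq_len(U)) {
      if (sd(ctx$S_std[, u]) == 0) {  # empty/constant score: no improvement
        r2[u] <- 0
        pval[u] <- 1
        next
      }
      f <- .fast_logistic(cbind(ctx$X_cov, score = ctx$S_std[, u]), y)
      r2[u] <- nagelkerke_r2(ll_int, f$loglik, n) - nk_cov
      pval[u] <- pchisq(2 * (f$loglik - f_cov$loglik), df = 1,
                        lower.tail = FALSE)
    }
  } else {
    tss <- sum((y - mean(y))^2)
    f_cov <- .fast_ols(ctx$X_cov, y)
    r2_cov <- 1 - f_cov$rss / tss
    df2 <- n - ncol(ctx$X_cov) - 1L
    for (u in seq_len(U)) {
      if (sd(ctx$S_std[, u]) == 0) {
        r2[u] <- 0
        pval[u] <- 1
        next
      }
      f <- .fast_ols(cbind(ctx$X_cov, score = ctx$S_std[, u]), y)
      r2[u] <- (1 - f$rss / tss) - r2_cov
      Fstat <- (f_cov$rss - f$rss) / (f$rss / df2)
      pval[u] <- pf(Fstat, 1, df2, lower.tail = FALSE)
    }
  }
  list(r2 = pmax(r2, 0), p = pval)
}

binom_loglik_intercept <- function(y) {
  p <- mean(y)
  sum(y) * log(p) + (length(y) - sum(y)) * log(1 - p)
}

#' Threshold scan of the polygenic score
#'
#' For each p-value threshold in `grid`, computes the standardized score from
#' the clumped panel, fits `outcome ~ score + covariates` (logistic for 0/1
#' outcomes, linear otherwise) on complete cases, and records the incremental
#' R-squared of the score: the Nagelkerke difference between the full and
#' covariate-only models for binary outcomes, the difference in squared
#' multiple correlation for continuous ones. The best threshold maximizes
#' incremental R-squared (smallest such threshold on ties). For binary
#' outcomes the best R-squared is also converted to the liability scale with
#' `K = P` (sample case fraction) unless a prevalence is supplied.
#'
#' @param panel A clumped `harmonized_panel`.
#' @param genotypes Target `genotype_matrix`.
#' @param data Cohort tibble with `id`, the outcome and covariates.
#' @param outcome Outcome column name.
#' @param covariates Covariate column names (default sex + first four PCs).
#' @param grid Threshold grid (default [default_grid()]).
#' @param family `"binomial"`, `"gaussian"`, or `NULL` to infer from the
#'   outcome values.
#' @param prevalence_k Population prevalence for the liability conversion;
#'   defaults to the sample case fraction.
#' @return A `pgs_scan` object; see [tidy()][generics::tidy] for the
#'   per-threshold table and [glance()][generics::glance] for the best-fit
#'   row.
#' @export
pgs_threshold_scan <- function(panel, genotypes, data, outcome,
                               covariates = c("sex", paste0("pc", 1:4)),
                               grid = default_grid(), family = NULL,
                               prevalence_k = NULL) {
  ctx <- scan_context(panel, genotypes, data, outcome, covariates, grid, family)
  fits <- fit_grid(ctx, ctx$y)

  u_of_grid <- match(ctx$grid_counts, ctx$counts)
  grid_tbl <- tibble(
    threshold = ctx$grid,
    n_snps = ctx$grid_counts,
    r2_obs = fits$r2[u_of_grid],
    p_model = fits$p[u_of_grid]
  )
  best_i <- which.max(grid_tbl$r2_obs)

  P <- if (ctx$family == "binomial") mean(ctx$y) else NA_real_
  K <- if (is.null(prevalence_k)) P else prevalence_k
  best_r2_liab <- if (ctx$family == "binomial") {
    liability_r2(grid_tbl$r2_obs[best_i], K, P)
  } else {
    NA_real_
  }

  structure(
    list(
      grid = grid_tbl,
      best_threshold = grid_tbl$threshold[best_i],
      best_n_snps = grid_tbl$n_snps[best_i],
      best_r2_obs = grid_tbl$r2_obs[best_i],
      best_r2_liab = best_r2_liab,
      best_p_model = grid_tbl$p_model[best_i],
      outcome = outcome, family = ctx$family, n = ctx$n,
      prevalence_k = K, case_fraction_p = P,
      covariates = covariates
    ),
    class = "pgs_scan"
  )
}

#' @method print pgs_scan
#' @export
print.pgs_scan <- function(x, ...) {
  cat(sprintf("<pgs_scan> %s (%s), n = %d\n", x$outcome, x$family, x$n))
  cat(sprintf("  best threshold %g: %d SNPs, incremental R2 = %.4g%s, model p = %.3g\n",
              x$best_threshold, x$best_n_snps, x$best_r2_obs,
              if (!is.na(x$best_r2_liab)) sprintf(" (liability %.4g)", x$best_r2_liab) else "",
              x$best_p_model))
  if (!is.null(x$empirical_p)) {
    cat(sprintf("  permutation empirical p = %.4g (N = %d)\n",
                x$empirical_p, x$n_permutations))
  }
  invisible(x)
}

#' Permutation empirical p-value for the best-fit threshold
#'
#' Permutes the outcome across individuals (covariate rows stay attached to
#' their individuals) `n_perm` times, reruns the full grid scan per
#' permutation, and records the best (smallest) model p-value each time. The
#' empirical p-value is `(1 + #[permuted best p <= observed best p]) /
#' (n_perm + 1)`, which accounts jointly for the number of thresholds tested
#' and the optimization-induced overfitting.
#'
#' @inheritParams pgs_threshold_scan
#' @param n_perm Number of permutations (default 11000).
#' @param seed Integer seed.
#' @return A `pgs_scan` object with `empirical_p`, `n_permutations` and the
#'   permutation null distribution `perm_best_p` added.
#' @export
permutation_empirical_p <- function(panel, genotypes, data, outcome,
                                    covariates = c("sex", paste0("pc", 1:4)),
                                    grid = default_grid(), family = NULL,
                                    n_perm = 11000, seed = 1L,
                                    prevalence_k = NULL) {
  n_perm <- check_count(n_perm, "n_perm")
  scan <- pgs_threshold_scan(panel, genotypes, data, outcome, covariates,
                             grid, family, prevalence_k)
  ctx <- scan_context(panel, genotypes, data, outcome, covariates, grid,
                      scan$family)

  perm_best <- numeric(n_perm)
  with_substream(seed, "permutation", {
    for (b in seq_len(n_perm)) {
      yb <- ctx$y[sample.int(ctx$n)]
      perm_best[b] <- min(fit_grid(ctx, yb)$p)
    }
  })

  scan$empirical_p <- (1 + sum(perm_best <= scan$best_p_model)) / (n_perm + 1)
  scan$n_permutations <- n_perm
  scan$perm_best_p <- perm_best
  scan
}
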