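# Independent reference implementations and fixture builders used across the
# suite. These deliberately share no code with the package internals.

options(pgsmed.quiet = TRUE)

# --- greedy clumping reference ------------------------------------------------
# Operates on an explicit r-squared matrix and plain loops; the package
# implementation works from dosages and window arithmetic instead.
oracle_clump <- function(meta, r2mat, window_bp = 250000, r2_thr = 0.1) {
  m <- nrow(meta)
  status <- rep("free", m)
  ord <- order(meta$p, meta$pos, meta$snp_id)
  for (k in ord) {
    if (status[k] != "free") next
    status[k] <- "index"
    for (j in seq_len(m)) {
      if (status[j] != "free") next
      if (meta$chrom[j] != meta$chrom[k]) next
      if (abs(meta$pos[j] - meta$pos[k]) > window_bp) next
      if (r2mat[j, k] > r2_thr) status[j] <- "pruned"
    }
  }
  meta$snp_id[status == "index"]
}

# --- hand-rolled Newton-Raphson logistic fit ---------------------------------
oracle_logistic <- function(X, y, maxit = 50, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    mu <- 1 / (1 + exp(-X %*% beta))
    grad <- t(X) %*% (y - mu)
    W <- as.vector(mu * (1 - mu))
    H <- t(X) %*% (X * W)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.vector(beta)
}

# --- numeric-integration truth for binary-outcome mediation -------------------
# E[Y(t, M(t'))] with M(t') ~ N(base_m + a t', sigma^2) and a logistic outcome
# model, integrated by Simpson's rule over the standardized mediator residual.
oracle_binary_mediation <- function(base_m, a, sigma, base_y, cp, b, t0 = 0, t1 = 1,
                                    n_grid = 201) {
  x <- seq(-8, 8, length.out = n_grid)
  h <- x[2] - x[1]
  w <- rep(c(2, 4), length.out = n_grid)
  w[1] <- w[n_grid] <- 1
  w <- w * h / 3 * dnorm(x)

  Ey <- function(t, tp) {
    # n x n_grid matrix of outcome probabilities, averaged over profiles
    eta <- outer(base_y + cp * t + b * (base_m + a * tp), b * sigma * x, `+`)
    mean(plogis(eta) %*% w)
  }
  acme <- ((Ey(t0, t1) - Ey(t0, t0)) + (Ey(t1, t1) - Ey(t1, t0))) / 2
  ade <- ((Ey(t1, t0) - Ey(t0, t0)) + (Ey(t1, t1) - Ey(t0, t1))) / 2
  c(total = acme + ade, ade = ade, acme = acme)
}

# --- per-person numeric integration of the random-intercept likelihood -------
oracle_glmm_loglik <- function(d, beta, sigma2, n_grid = 10001) {
  X <- cbind(1, d$std_score, d$age_u, d$sex, d$std_score * d$age_u)
  eta_fix <- as.vector(X %*% beta)
  sd_u <- sqrt(sigma2)
  u <- seq(-10 * max(sd_u, 0.02), 10 * max(sd_u, 0.02), length.out = n_grid)
  du <- u[2] - u[1]
  phi <- dnorm(u, 0, max(sd_u, 1e-8))
  ll <- 0
  for (i in unique(d$id)) {
    rows <- which(d$id == i)
    # log P(y_i | u) on the grid
    lp <- rep(0, n_grid)
    for (r in rows) {
      pr <- plogis(eta_fix[r] + u)
      lp <- lp + if (d$outcome[r] == 1) log(pr) else log1p(-pr)
    }
    ll <- ll + log(sum(exp(lp) * phi) * du)
  }
  ll
}

# --- small fixture builders ---------------------------------------------------
tiny_study <- function(n = 400, m = 100, n_causal = max(1, m %/% 5), seed = 11, ...) {
  cfg <- sim_config(n_individuals = n, n_variants = m, n_causal = n_causal,
                    ld_block_size = 10, seed = seed, ...)
  simulate_study(cfg, mar = FALSE)
}

# harmonized panel straight from generator output (no file round trip)
tiny_panel <- function(study) {
  apply_clump_all <- remove_strand_ambiguous(study$sumstats)
  harmonize(apply_clump_all, study$genotypes)
}

# genotype matrix from an explicit dosage matrix, 5 kb spacing
geno_from_matrix <- function(dos, pos = NULL, chrom = "1") {
  m <- ncol(dos)
  if (is.null(colnames(dos))) colnames(dos) <- sprintf("v%03d", seq_len(m))
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("s%03d", seq_len(nrow(dos)))
  genotype_matrix(dos, tibble::tibble(
    snp_id = colnames(dos), chrom = chrom,
    pos = pos %||% (5000L * seq_len(m)),
    ref = "A", alt = "G", maf = colMeans(dos, na.rm = TRUE) / 2
  ))
}

# panel rows for hand-built fixtures
panel_from <- function(geno, beta, p, flip = FALSE) {
  v <- geno$variants
  structure(
    tibble::tibble(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
                   beta = beta, p = p, eaf = v$maf,
                   flip = rep_len(flip, nrow(v))),
    class = c("harmonized_panel", class(tibble::tibble()))
  )
}

# bare-bones sumstats builder for QC fixtures
new_sumstats_fixture <- function(snp_id = sprintf("rs%d", seq_along(a1)),
                                 a1, a2, beta = rep(0.1, length(a1)),
                                 p = rep(0.01, length(a1)),
                                 pos = 1000L * seq_along(a1)) {
  structure(
    tibble::tibble(snp_id = snp_id, chrom = "1", pos = pos,
                   effect_allele = a1, other_allele = a2,
                   eaf = 0.3, beta = beta, se = 0.01, p = p),
    class = c("sumstats", class(tibble::tibble()))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
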