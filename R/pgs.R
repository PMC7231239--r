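# Quality control, harmonization, LD clumping and weighted-sum polygenic
# scoring.

#' Remove strand-ambiguous variants
#'
#' Drops variants whose allele pair is self-complementary ({A,T} or {C,G}),
#' which cannot be resolved across strand conventions; count is logged.
#'
#' @param sumstats A `sumstats` tibble.
#' @return Filtered `sumstats`.
#' @export
remove_strand_ambiguous <- function(sumstats) {
  amb <- is_ambiguous_pair(sumstats$effect_allele, sumstats$other_allele)
  log_info(sprintf("remove_strand_ambiguous: removed %d of %d variants",
                   sum(amb), length(amb)))
  out <- sumstats[!amb, ]
  if (nrow(out) == 0) {
    warn("remove_strand_ambiguous: no variants remain", class = "pgsmed_qc_warning")
  }
  out
}

is_ambiguous_pair <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  toupper(a2) == unname(comp[toupper(a1)])
}

#' Harmonize summary statistics with the target panel
#'
#' Matches variants by id and fixes the dosage orientation of each: if the
#' discovery effect allele is the target ALT allele the dosage is used as-is;
#' if it is the target REF allele the dosage is flipped (`2 - d`); variants
#' whose alleles do not match `{REF, ALT}` are dropped with a logged count.
#' Strand-ambiguous variants must be removed first.
#'
#' @param sumstats A `sumstats` tibble (post [remove_strand_ambiguous()]).
#' @param genotypes A `genotype_matrix`.
#' @return A `harmonized_panel` tibble: snp_id, chrom, pos, beta, p, eaf,
#'   flip (logical).
#' @export
harmonize <- function(sumstats, genotypes) {
  amb <- is_ambiguous_pair(sumstats$effect_allele, sumstats$other_allele)
  if (any(amb)) {
    warn(sprintf("harmonize: %d strand-ambiguous variant(s) present; removing",
                 sum(amb)), class = "pgsmed_qc_warning")
    sumstats <- sumstats[!amb, ]
  }
  v <- genotypes$variants
  i <- match(sumstats$snp_id, v$snp_id)
  present <- !is.na(i)
  s <- sumstats[present, ]
  tv <- v[i[present], ]

  a1 <- toupper(s$effect_allele)
  a2 <- toupper(s$other_allele)
  as_is <- a1 == toupper(tv$alt) & a2 == toupper(tv$ref)
  flipped <- a1 == toupper(tv$ref) & a2 == toupper(tv$alt)
  keep <- as_is | flipped

  log_info(sprintf(
    "harmonize: %d matched by id (%d absent from target), %d allele-mismatch dropped, %d flipped",
    nrow(s), sum(!present), sum(!keep), sum(flipped)
  ))
  out <- tibble(
    snp_id = s$snp_id[keep],
    chrom = tv$chrom[keep],
    pos = tv$pos[keep],
    beta = s$beta[keep],
    p = s$p[keep],
    eaf = s$eaf[keep],
    flip = flipped[keep]
  )
  if (nrow(out) == 0) {
    abort("harmonize: zero variants matched between discovery and target",
          class = "pgsmed_input_error")
  }
  structure(out, class = c("harmonized_panel", class(tibble())))
}

#' Squared-correlation linkage disequilibrium between two variants
#'
#' Squared Pearson correlation of dosages over pairwise-complete individuals.
#' A monomorphic variant yields r-squared 0 with a warning.
#'
#' @param genotypes A `genotype_matrix`.
#' @param id1,id2 Variant ids (or column indices).
#' @return A single r-squared value in `[0, 1]`.
#' @export
estimate_ld <- function(genotypes, id1, id2) {
  col <- function(id) {
    j <- if (is.character(id)) match(id, genotypes$variants$snp_id) else id
    if (is.na(j)) abort(sprintf("unknown variant id: %s", id),
                        class = "pgsmed_input_error")
    genotypes$dosage[, j]
  }
  x <- col(id1)
  y <- col(id2)
  ok <- !is.na(x) & !is.na(y)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    warn("estimate_ld: monomorphic variant; r2 defined as 0",
         class = "pgsmed_qc_warning")
    return(0)
  }
  cor(x[ok], y[ok])^2
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unpruned variant with the smallest p-value as an
#' index variant (ties broken by smaller position, then lexicographic id) and
#' prunes every unpruned variant on the same chromosome within
#' `window_kb` kb on either side whose dosage r-squared with the index exceeds
#' `r2_threshold`. LD is computed in the target sample itself.
#'
#' @param panel A `harmonized_panel`.
#' @param genotypes The target `genotype_matrix`.
#' @param window_kb Half-window in kb around the index position, bounds
#'   inclusive (default 250).
#' @param r2_threshold LD pruning threshold (default 0.1).
#' @return A `clump_result` tibble: `index_snp` (retained, in selection
#'   order), `p`, `pruned` (list column of pruned variant ids assigned to
#'   that index).
#' @export
clump <- function(panel, genotypes, window_kb = 250, r2_threshold = 0.1) {
  m <- nrow(panel)
  j <- match(panel$snp_id, genotypes$variants$snp_id)
  if (anyNA(j)) {
    abort("clump: panel contains variants absent from the genotype matrix",
          class = "pgsmed_input_error")
  }
  # deterministic processing order: p, then position, then id
  ord <- order(panel$p, panel$pos, panel$snp_id)
  window <- window_kb * 1000

  state <- rep.int(0L, m)  # 0 free, 1 index, 2 pruned
  assigned_to <- integer(m)
  dosage <- genotypes$dosage

  for (k in ord) {
    if (state[k] != 0L) next
    state[k] <- 1L
    cand <- which(state == 0L &
                    panel$chrom == panel$chrom[k] &
                    abs(panel$pos - panel$pos[k]) <= window)
    if (length(cand) == 0) next
    x <- dosage[, j[k]]
    sx <- sd(x, na.rm = TRUE)
    if (is.na(sx) || sx == 0) next  # monomorphic index prunes nothing (r2 = 0)
    r2 <- suppressWarnings(
      cor(x, dosage[, j[cand], drop = FALSE], use = "pairwise.complete.obs")
    )^2
    r2[is.na(r2)] <- 0
    hits <- cand[r2 > r2_threshold]
    state[hits] <- 2L
    assigned_to[hits] <- k
  }

  idx <- ord[state[ord] == 1L]  # selection order
  out <- tibble(
    index_snp = panel$snp_id[idx],
    p = panel$p[idx],
    pruned = lapply(idx, function(k) panel$snp_id[assigned_to == k & state == 2L])
  )
  log_info(sprintf("clump: retained %d index variants of %d (window %g kb, r2 > %g pruned)",
                   nrow(out), m, window_kb, r2_threshold))
  structure(out, class = c("clump_result", class(tibble())))
}

#' Restrict a harmonized panel to clump index variants
#'
#' @param panel A `harmonized_panel`.
#' @param clump_result Result of [clump()].
#' @return The panel rows for the retained index variants (input order).
#' @export
apply_clump <- function(panel, clump_result) {
  out <- panel[panel$snp_id %in% clump_result$index_snp, ]
  structure(out, class = c("harmonized_panel", class(tibble())))
}

#' Compute the weighted-sum polygenic score
#'
#' Includes panel variants with discovery `p <= p_threshold`. The raw score
#' is `sum_j beta_j * dosage_ij` with dosages oriented to the effect allele
#' (flipped variants contribute `beta * (2 - d)`); a missing dosage is
#' replaced by twice the effect-allele frequency computed in the target
#' sample. The standardized score (mean 0, SD 1 over the sample) is returned
#' alongside.
#'
#' @param panel A `harmonized_panel` (typically clumped).
#' @param genotypes The target `genotype_matrix`.
#' @param p_threshold Discovery p-value inclusion threshold (default 1).
#' @return A `pgs_vector` tibble: sample_id, raw_score, std_score; attributes
#'   `n_snps` and `p_threshold`.
#' @export
score_pgs <- function(panel, genotypes, p_threshold = 1) {
  use <- panel$p <= p_threshold
  d <- oriented_dosage(panel[use, , drop = FALSE], genotypes)
  raw <- if (sum(use) == 0) {
    warn("score_pgs: no variants pass the threshold; scores are all zero",
         class = "pgsmed_qc_warning")
    rep(0, nrow(genotypes$dosage))
  } else {
    as.vector(d %*% panel$beta[use])
  }
  std <- if (length(raw) > 1 && sd(raw) > 0) as.vector(scale(raw)) else {
    if (sum(use) > 0 && length(raw) > 1) {
      warn("score_pgs: score is constant; std_score set to 0",
           class = "pgsmed_qc_warning")
    }
    rep(0, length(raw))
  }
  structure(
    tibble(sample_id = genotypes$samples, raw_score = raw, std_score = std),
    n_snps = sum(use), p_threshold = p_threshold,
    class = c("pgs_vector", class(tibble()))
  )
}

# effect-allele-oriented dosage matrix with in-sample mean imputation
oriented_dosage <- function(panel, genotypes) {
  j <- match(panel$snp_id, genotypes$variants$snp_id)
  d <- genotypes$dosage[, j, drop = FALSE]
  if (any(panel$flip)) {
    d[, panel$flip] <- 2 - d[, panel$flip, drop = FALSE]
  }
  if (anyNA(d)) {
    eaf_target <- colMeans(d, na.rm = TRUE) / 2
    for (k in which(colSums(is.na(d)) > 0)) {
      d[is.na(d[, k]), k] <- 2 * eaf_target[k]
    }
  }
  d
}
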