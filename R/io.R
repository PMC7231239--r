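# Readers/writers for the three input formats and result tables. All format
# dialect decisions (column names, missing token, 1-based positions) live
# here.

sumstats_cols <- c("SNP", "CHR", "BP", "A1", "A2", "EAF", "BETA", "SE", "P")

#' Read discovery GWAS summary statistics
#'
#' Expects a tab-delimited file with header columns SNP, CHR, BP, A1, A2,
#' EAF, BETA, SE, P (EAF optional). A1 is the effect allele. Rows failing
#' validation are dropped with a logged count: unparsable numerics, identical
#' alleles, alleles outside A/C/G/T (indels, multi-allelic), `p` outside
#' `(0, 1]`, or non-positive `se`. Input variant order is preserved.
#'
#' @param path File path.
#' @return A `sumstats` tibble: snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, p.
#' @export
read_sumstats <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = "NA", progress = FALSE)
  missing_cols <- setdiff(setdiff(sumstats_cols, "EAF"), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("summary statistics file is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "pgsmed_format_error")
  }
  n0 <- nrow(raw)
  x <- tibble(
    snp_id = raw$SNP,
    chrom = raw$CHR,
    pos = suppressWarnings(as.integer(raw$BP)),
    effect_allele = toupper(raw$A1),
    other_allele = toupper(raw$A2),
    eaf = if ("EAF" %in% names(raw)) suppressWarnings(as.numeric(raw$EAF)) else NA_real_,
    beta = suppressWarnings(as.numeric(raw$BETA)),
    se = suppressWarnings(as.numeric(raw$SE)),
    p = suppressWarnings(as.numeric(raw$P))
  )
  keep <- !is.na(x$snp_id) & !is.na(x$pos) &
    !is.na(x$beta) & !is.na(x$se) & x$se > 0 &
    !is.na(x$p) & x$p > 0 & x$p <= 1 &
    x$effect_allele %in% c("A", "C", "G", "T") &
    x$other_allele %in% c("A", "C", "G", "T") &
    x$effect_allele != x$other_allele
  if (any(!keep)) {
    warn(sprintf("read_sumstats: dropped %d of %d rows failing validation",
                 sum(!keep), n0), class = "pgsmed_qc_warning")
  }
  x <- x[keep, ]
  if (anyDuplicated(x$snp_id)) {
    dup <- duplicated(x$snp_id)
    warn(sprintf("read_sumstats: dropped %d duplicated snp id(s)", sum(dup)),
         class = "pgsmed_qc_warning")
    x <- x[!dup, ]
  }
  log_info(sprintf("read_sumstats: %d variants retained from %s", nrow(x), path))
  new_sumstats(x)
}

#' Write summary statistics
#'
#' Tab-delimited, header SNP CHR BP A1 A2 EAF BETA SE P, missing token "NA".
#'
#' @param sumstats A `sumstats` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- tibble(SNP = sumstats$snp_id, CHR = sumstats$chrom, BP = sumstats$pos,
                A1 = sumstats$effect_allele, A2 = sumstats$other_allele,
                EAF = sumstats$eaf, BETA = sumstats$beta, SE = sumstats$se,
                P = sumstats$p)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read target genotypes
#'
#' Reads either a VCF (v4.2 subset: CHROM, POS, ID, REF, ALT, GT and optional
#' DS) or a plain dosage matrix (tab-delimited; first column `sample_id`,
#' remaining columns one variant each, header = variant ids). GT fields are
#' converted to ALT-allele dosage in `{0, 1, 2}`; `./.` becomes missing; when
#' both DS and GT are present, DS wins. Indel and multi-allelic records are
#' dropped with a logged count. Variant order is preserved.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"matrix"`.
#' @param variants For `format = "matrix"`, an optional tibble of variant
#'   metadata (snp_id, chrom, pos, ref, alt) matched by snp_id.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix"),
                           variants = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_matrix(path, variants)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n0 <- nrow(fix)
  snv <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snv)) {
    warn(sprintf("read_genotypes: dropped %d non-SNV/multi-allelic record(s)",
                 sum(!snv)), class = "pgsmed_qc_warning")
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)

  gt_to_dosage <- function(g) {
    g <- sub("\\|", "/", g)
    unname(c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)[g])
  }
  dos <- matrix(gt_to_dosage(gt), nrow = nrow(gt), dimnames = dimnames(gt))
  if (!is.null(ds) && any(!is.na(ds))) {
    use <- !is.na(ds)
    dos[use] <- ds[use]  # DS preferred over GT where present
  }
  dos <- t(dos)[, snv, drop = FALSE]  # samples x variants

  v <- tibble(
    snp_id = fix$ID[snv], chrom = fix$CHROM[snv],
    pos = as.integer(fix$POS[snv]), ref = fix$REF[snv], alt = fix$ALT[snv]
  )
  v$maf <- colMeans(dos, na.rm = TRUE) / 2
  log_info(sprintf("read_genotypes: %d samples x %d variants from %s (%d records dropped)",
                   nrow(dos), ncol(dos), path, n0 - sum(snv)))
  genotype_matrix(dosage = dos, variants = v)
}

read_genotypes_matrix <- function(path, variants = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()
  ), na = "NA", progress = FALSE)
  if (!"sample_id" %in% names(x)) {
    abort("dosage matrix file must have a `sample_id` first column",
          class = "pgsmed_format_error")
  }
  ids <- x$sample_id
  dos <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(dos) <- ids
  if (is.null(variants)) {
    variants <- tibble(snp_id = colnames(dos), chrom = NA_character_,
                       pos = seq_len(ncol(dos)), ref = NA_character_,
                       alt = NA_character_)
  } else {
    variants <- variants[match(colnames(dos), variants$snp_id), ]
  }
  variants$maf <- colMeans(dos, na.rm = TRUE) / 2
  genotype_matrix(dosage = dos, variants = variants)
}

#' Write genotypes as VCF
#'
#' Plain-text VCF v4.2 subset with GT (dosages rounded to `{0, 1, 2}` as
#' 0/0, 0/1, 1/1; missing as ./.) and optionally a DS field carrying the
#' numeric dosage.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path (`.vcf`).
#' @param dosage_field Also emit DS (default FALSE).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path, dosage_field = FALSE) {
  v <- genotypes$variants
  d <- genotypes$dosage
  n <- nrow(d)

  gt_codes <- c("0/0", "0/1", "1/1")
  fmt_one <- function(j) {
    g <- d[, j]
    gt <- ifelse(is.na(g), "./.", gt_codes[pmin(pmax(round(g), 0), 2) + 1L])
    if (dosage_field) paste0(gt, ":", ifelse(is.na(g), ".", format(g, trim = TRUE))) else gt
  }
  fields <- vapply(seq_len(ncol(d)), function(j) paste(fmt_one(j), collapse = "\t"),
                   character(1))
  body <- paste(v$chrom, v$pos, v$snp_id, v$ref, v$alt, ".", "PASS", ".",
                if (dosage_field) "GT:DS" else "GT", fields, sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pgsmed",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (dosage_field) '##FORMAT=<ID=DS,Number=1,Type=Float,Description="ALT dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write the phenotype-covariate table
#'
#' Tab-delimited with a header row and "NA" as the missing token.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  x <- readr::read_tsv(path, na = "NA", progress = FALSE,
                       col_types = readr::cols(id = readr::col_character(),
                                               .default = readr::col_guess()))
  if (!"id" %in% names(x)) {
    abort("cohort table must have an `id` column", class = "pgsmed_format_error")
  }
  x
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Align genotype samples with the cohort table
#'
#' Intersects sample ids; the genotype file order wins. Dropped counts on
#' both sides are logged.
#'
#' @param genotypes A `genotype_matrix`.
#' @param cohort A cohort tibble with an `id` column.
#' @return List with `genotypes` and `cohort` restricted to the shared ids,
#'   in genotype order.
#' @export
align_samples <- function(genotypes, cohort) {
  shared <- genotypes$samples[genotypes$samples %in% cohort$id]
  if (length(shared) == 0) {
    abort("no shared sample ids between genotypes and cohort",
          class = "pgsmed_input_error")
  }
  log_info(sprintf("align_samples: %d shared ids (%d genotype-only, %d cohort-only dropped)",
                   length(shared), length(genotypes$samples) - length(shared),
                   nrow(cohort) - length(shared)))
  keep <- match(shared, genotypes$samples)
  g <- genotype_matrix(genotypes$dosage[keep, , drop = FALSE], genotypes$variants)
  list(genotypes = g, cohort = cohort[match(shared, cohort$id), ])
}
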