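# End-to-end orchestration: simulate (or read) -> QC -> clump -> score ->
# threshold scan -> association -> longitudinal GLMM -> mediation, with every
# intermediate artifact and a run-metadata sidecar written to a directory.

#' Configure a pipeline run
#'
#' Exactly one of `input_paths` (list with `sumstats`, `genotypes`,
#' `cohort`) or `simulation` (a [sim_config()]) must be supplied.
#'
#' @param input_paths Named list of the three input file paths, or `NULL`.
#' @param simulation A [sim_config()], or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param outcomes Outcome columns to analyse (default: the binary roster
#'   plus the five cognition scales present in the cohort).
#' @param grid Threshold grid for the scan.
#' @param n_perm Permutations for empirical p-values (0 skips them).
#' @param n_boot Mediation resamples.
#' @param glmm_behaviors Behavior stems for the longitudinal model (default
#'   `"fasting"`; `character(0)` skips).
#' @param clump_kb,clump_r2 Clumping window (kb) and r-squared threshold.
#' @param seed Top-level integer seed; per-stage substreams derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(input_paths = NULL, simulation = NULL,
                       out_dir = tempfile("pgsmed_run_"),
                       outcomes = NULL, grid = default_grid(),
                       n_perm = 0, n_boot = 1000,
                       glmm_behaviors = "fasting",
                       clump_kb = 250, clump_r2 = 0.1, seed = 1L) {
  if (is.null(input_paths) == is.null(simulation)) {
    abort("supply exactly one of `input_paths` or `simulation`",
          class = "pgsmed_config_error")
  }
  if (!is.null(input_paths)) {
    stopifnot(all(c("sumstats", "genotypes", "cohort") %in% names(input_paths)))
  }
  structure(
    list(input_paths = input_paths, simulation = simulation, out_dir = out_dir,
         outcomes = outcomes, grid = grid, n_perm = n_perm, n_boot = n_boot,
         glmm_behaviors = glmm_behaviors, clump_kb = clump_kb,
         clump_r2 = clump_r2, seed = check_count(seed, "seed", min = 0)),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing every intermediate artifact
#' (tab-delimited tables, one VCF) plus `run_metadata.yaml` (seed, grid,
#' thresholds, package version, per-stage counts) into `config$out_dir`.
#' Re-running the same configuration reproduces all outputs bit-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the output directory and the in-memory
#'   results (`association`, `scans`, `glmm`, `mediation`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = config$seed, clump_kb = config$clump_kb,
               clump_r2 = config$clump_r2, n_perm = config$n_perm,
               n_boot = config$n_boot,
               grid = sprintf("%d thresholds in [%g, %g]",
                              length(config$grid), min(config$grid), max(config$grid)),
               package_version = as.character(utils::packageVersion("pgsmed")),
               stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            class = "pgsmed_pipeline_error", parent = e)
    })
  }

  # -- inputs ----------------------------------------------------------------
  if (!is.null(config$simulation)) {
    study <- stage("simulate", simulate_study(config$simulation))
    sumstats <- study$sumstats
    genotypes <- study$genotypes
    cohort <- study$cohort
    write_sumstats(sumstats, file.path(config$out_dir, "sumstats.tsv"))
    write_vcf(genotypes, file.path(config$out_dir, "genotypes.vcf"))
    write_cohort(cohort, file.path(config$out_dir, "cohort.tsv"))
  } else {
    sumstats <- stage("read_sumstats", read_sumstats(config$input_paths$sumstats))
    genotypes <- stage("read_genotypes", read_genotypes(config$input_paths$genotypes))
    cohort <- stage("read_cohort", read_cohort(config$input_paths$cohort))
  }
  meta$stages$inputs <- list(n_variants = nrow(sumstats),
                             n_samples = length(genotypes$samples),
                             n_cohort = nrow(cohort))

  # -- QC, harmonization, clumping ------------------------------------------
  sumstats_qc <- stage("qc", remove_strand_ambiguous(sumstats))
  panel <- stage("harmonize", harmonize(sumstats_qc, genotypes))
  clumped <- stage("clump", clump(panel, genotypes,
                                  window_kb = config$clump_kb,
                                  r2_threshold = config$clump_r2))
  panel_c <- apply_clump(panel, clumped)
  readr::write_tsv(
    tibble(index_snp = clumped$index_snp, p = clumped$p,
           pruned = vapply(clumped$pruned, paste, character(1), collapse = ",")),
    file.path(config$out_dir, "clump_report.tsv"), progress = FALSE
  )
  meta$stages$clump <- list(n_harmonized = nrow(panel), n_index = nrow(panel_c))

  # -- baseline score at threshold 1 ----------------------------------------
  pgs1 <- stage("score", score_pgs(panel_c, genotypes, p_threshold = 1))
  readr::write_tsv(pgs1, file.path(config$out_dir, "scores_pt1.tsv"),
                   progress = FALSE)

  # -- per-outcome scan + association ---------------------------------------
  outcomes <- config$outcomes %||%
    intersect(c(names(default_prevalences()), names(continuous_outcomes())),
              names(cohort))
  scans <- list()
  assoc <- list()
  for (oc in outcomes) {
    sc <- stage(paste0("scan:", oc), {
      if (config$n_perm > 0) {
        permutation_empirical_p(panel_c, genotypes, cohort, oc,
                                grid = config$grid, n_perm = config$n_perm,
                                seed = derive_seed(config$seed, paste0("perm-", oc)))
      } else {
        pgs_threshold_scan(panel_c, genotypes, cohort, oc, grid = config$grid)
      }
    })
    scans[[oc]] <- sc
    best_scores <- score_pgs(panel_c, genotypes, sc$best_threshold)
    d <- dplyr::inner_join(cohort,
                           tibble(id = best_scores$sample_id,
                                  std_score = best_scores$std_score),
                           by = "id")
    assoc[[oc]] <- stage(paste0("associate:", oc), fit_association(d, oc))
  }
  association <- fdr_across_phenotypes(dplyr::bind_rows(assoc))
  association$best_threshold <- vapply(scans[outcomes], `[[`, numeric(1), "best_threshold")
  association$n_snps <- vapply(scans[outcomes], `[[`, numeric(1), "best_n_snps")
  association$empirical_p <- vapply(scans[outcomes],
                                    function(s) s$empirical_p %||% NA_real_,
                                    numeric(1))
  readr::write_tsv(association, file.path(config$out_dir, "association.tsv"),
                   progress = FALSE)
  scan_tbl <- dplyr::bind_rows(lapply(scans, glance))
  readr::write_tsv(scan_tbl, file.path(config$out_dir, "scan_summary.tsv"),
                   progress = FALSE)

  # -- longitudinal GLMM -----------------------------------------------------
  glmm <- list()
  for (beh in config$glmm_behaviors) {
    lt <- build_long_table(cohort, pgs1, beh)
    glmm[[beh]] <- stage(paste0("glmm:", beh), fit_glmm_interaction(lt))
  }
  if (length(glmm) > 0) {
    readr::write_tsv(dplyr::bind_rows(lapply(glmm, glance), .id = "behavior"),
                     file.path(config$out_dir, "glmm_summary.tsv"),
                     progress = FALSE)
  }

  # -- mediation -------------------------------------------------------------
  mediation <- list()
  for (oc in outcomes) {
    best_scores <- score_pgs(panel_c, genotypes, scans[[oc]]$best_threshold)
    d <- dplyr::inner_join(cohort,
                           tibble(id = best_scores$sample_id,
                                  std_score = best_scores$std_score),
                           by = "id")
    mediation[[oc]] <- stage(paste0("mediate:", oc), estimate_mediation(
      d, oc, n_resamples = config$n_boot,
      seed = derive_seed(config$seed, paste0("mediate-", oc))
    ))
  }
  med_tbl <- mediation_report(mediation)
  readr::write_tsv(med_tbl, file.path(config$out_dir, "mediation.tsv"),
                   progress = FALSE)

  meta$stages$outcomes <- outcomes
  yaml::write_yaml(meta, file.path(config$out_dir, "run_metadata.yaml"))

  invisible(list(out_dir = config$out_dir, association = association,
                 scans = scans, glmm = glmm, mediation = mediation,
                 mediation_table = med_tbl))
}
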