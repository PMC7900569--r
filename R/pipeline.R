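#' Run the laterality-analysis pipeline end to end
#'
#' Orchestrates the three evaluations on a cohort power table: laterality
#' indices with control-baseline correction, the band-wise 2 x 4 factorial
#' ANOVA with pooled-bootstrap significance plus the per-cell bootstrap
#' tests with FDR control, and the leave-one-out linear-SVM classification
#' in both scenarios (left-focus vs control, right-focus vs control), with
#' the dipole-concordance summary of the packaged patient table. Output
#' tables are written as CSV into `out_dir` along with a small provenance
#' file recording the seed.
#'
#' @param cohort Long power tibble ([simulate_power_cohort()] /
#'   [read_power_table()]), or `NULL` to simulate one from `config`.
#' @param evaluation Which stage(s) to run: `"laterality"` (LI tables),
#'   `"stats"` (ANOVA + bootstrap tests), `"classify"`, `"concordance"`, or
#'   `"all"`.
#' @param config A [synth_config()], used when `cohort` is `NULL`.
#' @param n_resamples Bootstrap resamples for the statistical stage.
#' @param seed Global seed recorded in provenance and used for every
#'   stochastic stage.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list of in-memory results (`li`, `li_corrected`, `anova`,
#'   `tests`, `classification`, `concordance`; stages not run are absent),
#'   invisibly if `out_dir` is set.
#' @export
run_pipeline <- function(cohort = NULL,
                         evaluation = c("all", "laterality", "stats",
                                        "classify", "concordance"),
                         config = synth_config(), n_resamples = 2000,
                         seed = 1L, out_dir = NULL) {
  evaluation <- match.arg(evaluation)
  results <- list(seed = seed)

  if (evaluation == "concordance") {
    results$concordance <- ecd_concordance(load_table1())
    return(write_pipeline_outputs(results, out_dir))
  }

  if (is.null(cohort)) {
    config$seed <- seed
    cohort <- simulate_power_cohort(config)
  }
  li <- li_table(cohort)
  baseline <- ctr_baseline(li)
  patients <- dplyr::filter(li, .data$group != "CTR")
  li_corr <- baseline_correct(patients, baseline)
  results$li <- li
  results$li_corrected <- li_corr

  if (evaluation %in% c("stats", "all")) {
    results$anova <- li_anova_table(li_corr, n_resamples = n_resamples,
                                    seed = seed)
    results$tests <- li_group_tests(li_corr, n_resamples = n_resamples,
                                    seed = seed)
  }
  if (evaluation %in% c("classify", "all")) {
    m <- li_matrix(li)
    groups <- attr(m, "groups")
    results$classification <- purrr::map(
      stats::setNames(c("LtMTLE", "RtMTLE"), c("Lt_vs_CTR", "Rt_vs_CTR")),
      function(pos) {
        keep <- groups %in% c(pos, "CTR")
        loocv_svm(m[keep, , drop = FALSE], groups[keep], positive = pos,
                  seed = seed)
      })
  }
  if (evaluation == "all") {
    results$concordance <- ecd_concordance(load_table1())
  }
  write_pipeline_outputs(results, out_dir)
}

write_pipeline_outputs <- function(results, out_dir) {
  if (is.null(out_dir)) return(results)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    readr::write_csv(dplyr::mutate(x, dplyr::across(
      dplyr::where(is.factor), as.character)),
      file.path(out_dir, name), progress = FALSE)
  }
  if (!is.null(results$li)) wr(results$li, "laterality_indices.csv")
  if (!is.null(results$li_corrected)) {
    wr(results$li_corrected, "laterality_indices_corrected.csv")
  }
  if (!is.null(results$anova)) wr(results$anova, "anova_bootstrap.csv")
  if (!is.null(results$tests)) wr(results$tests, "cell_tests.csv")
  if (!is.null(results$classification)) {
    for (sc in names(results$classification)) {
      fit <- results$classification[[sc]]
      wr(tidy(fit), paste0("loocv_predictions_", sc, ".csv"))
      wr(glance(fit), paste0("loocv_metrics_", sc, ".csv"))
      roc <- roc_curve(fit$predictions$posterior, fit$predictions$truth,
                       positive = fit$positive)
      wr(tidy(roc), paste0("roc_", sc, ".csv"))
    }
  }
  if (!is.null(results$concordance)) wr(results$concordance, "concordance.csv")
  writeLines(sprintf('{"seed": %d}', results$seed),
             file.path(out_dir, "provenance.json"))
  invisible(results)
}
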