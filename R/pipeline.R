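#' Run the full development-and-validation pipeline
#'
#' Orchestrates the computational parts of the three study phases on
#' supplied or simulated data: card sorts -> similarity matrix -> nonmetric
#' map -> cluster ladder -> bridging values -> rating summary -> sorter
#' reliability, then patient records -> decision-rule scoring -> validation
#' analytics (marginal logistic model, ROC/AUC, cut-off table, Cronbach's
#' alpha, pilot agreement). All artifacts are written as CSV/JSON under
#' `out_dir` and a JSON run report collects seeds, key statistics and every
#' warning raised. A single root `seed` is split into independent per-stage
#' seeds, so a rerun with the same inputs reproduces every number.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed.
#' @param sorts,ratings,patients Each may be `NULL` (simulate), a file path
#'   (read with the package readers) or a data frame.
#' @param k_max,k_min Cluster-ladder range (defaults 15 and 2).
#' @param k Cluster solution carried forward to bridging/rating summaries
#'   (default 6).
#' @param n_starts Random restarts for the map embedding.
#' @param config A [tool_config()].
#' @param ci_method AUC confidence-interval method.
#' @param sim_sorting,sim_patients Named-list overrides passed to
#'   [simulate_sorting()] / [simulate_patients()] when simulating.
#' @return An object of class `dtpd_run_report` (a list), also written to
#'   `out_dir/report.json`. On a stage failure the error names the stage and
#'   artifacts of completed stages remain on disk.
#' @export
run_pipeline <- function(out_dir, seed = 1, sorts = NULL, ratings = NULL,
                         patients = NULL, k_max = 15, k_min = 2, k = 6,
                         n_starts = 8, config = tool_config(),
                         ci_method = "delong",
                         sim_sorting = list(), sim_patients = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_seeds <- split_seed(seed, 4)
  names(stage_seeds) <- c("sorting", "ratings", "map", "patients")
  warnings_log <- character(0)
  timings <- list()
  report <- list(tool = "dtpd", version = as.character(utils::packageVersion("dtpd")),
                 root_seed = seed, stage_seeds = as.list(stage_seeds))

  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
              class = "dtpd_stage_error", parent = e)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    res
  }

  # ---- Phase 2: concept mapping ----
  truth_sorting <- NULL
  sorts_df <- run_stage("sorts", {
    if (is.null(sorts)) {
      sim <- do.call(simulate_sorting,
                     utils::modifyList(list(seed = stage_seeds[["sorting"]]), sim_sorting))
      truth_sorting <<- sim$truth
      sim$sorts
    } else if (is.character(sorts)) read_sorts(sorts) else validate_sorts(sorts)
  })
  write_table(sorts_df, file.path(out_dir, "sorts.csv"))

  sim_mat <- run_stage("similarity", build_similarity(sorts_df))
  write_similarity(sim_mat, file.path(out_dir, "similarity.csv"))
  report$n_items <- length(sim_mat$items)
  report$n_sorters <- sim_mat$n_sorters
  report$excluded_sorters <- sim_mat$excluded

  map <- run_stage("map", embed_map(sim_mat, seed = stage_seeds[["map"]],
                                    n_starts = n_starts))
  write_map(map, file.path(out_dir, "map.csv"))
  report$stress <- map$stress

  ladder <- run_stage("cluster", cluster_ladder(map, k_max = min(k_max, length(map$items)),
                                                k_min = k_min))
  write_table(ladder$assignments, file.path(out_dir, "cluster_ladder.csv"))
  solution <- ladder_solution(ladder, k)
  report$k <- k
  report$pile_counts <- as.list(pile_count_summary(sorts_df))

  bridging <- run_stage("bridge", bridging_values(map, sim_mat))
  write_table(bridging, file.path(out_dir, "bridging.csv"))
  cb <- cluster_bridging(bridging, solution)
  write_table(cb, file.path(out_dir, "cluster_bridging.csv"))
  report$mean_bridging <- mean(bridging$bridging, na.rm = TRUE)

  ratings_df <- run_stage("ratings", {
    if (is.null(ratings)) {
      means <- seq(3.2, 4.6, length.out = dplyr::n_distinct(solution$cluster))
      simulate_ratings(solution, means, seed = stage_seeds[["ratings"]])
    } else if (is.character(ratings)) read_ratings(ratings) else validate_ratings(ratings)
  })
  write_table(ratings_df, file.path(out_dir, "ratings.csv"))

  rating_sum <- run_stage("rate", rating_summary(ratings_df, solution))
  write_table(rating_sum$cluster_means, file.path(out_dir, "cluster_ratings.csv"))
  write_table(rating_sum$tests, file.path(out_dir, "rating_tests.csv"))
  report$bonferroni_threshold <- rating_sum$threshold

  rel <- run_stage("reliability", sorter_reliability(sorts_df))
  report$reliability <- list(mean_r = rel$mean_r, sb_corrected = rel$sb_corrected,
                             k = rel$k)

  # ---- Phase 3: scoring and validation ----
  truth_patients <- NULL
  patients_df <- run_stage("patients", {
    if (is.null(patients)) {
      sim <- do.call(simulate_patients,
                     utils::modifyList(list(seed = stage_seeds[["patients"]]), sim_patients))
      truth_patients <<- sim$truth
      sim$records
    } else if (is.character(patients)) read_patients(patients, config) else
      tibble::as_tibble(patients)
  })
  write_table(patients_df, file.path(out_dir, "patients.csv"))
  report$n_patients <- nrow(patients_df)

  decisions <- run_stage("score", score_patients(patients_df, config))
  write_table(decisions, file.path(out_dir, "decisions.csv"))
  write_table(score_distribution(decisions), file.path(out_dir, "score_distribution.csv"))
  report$referral_rate <- mean(decisions$referral)

  val <- run_stage("validate", validate_tool(patients_df, config,
                                             ci_method = ci_method, seed = seed))
  write_table(val$cutoffs, file.path(out_dir, "cutoff_table.csv"))
  write_table(val$roc$points, file.path(out_dir, "roc_points.csv"))
  write_table(val$gee$coefficients, file.path(out_dir, "model_coefficients.csv"))
  write_table(val$pilot_agreement, file.path(out_dir, "pilot_agreement.csv"))
  report$auc <- val$roc$auc
  report$auc_ci <- c(val$roc$ci_lower, val$roc$ci_upper)
  report$cronbach_alpha <- val$cronbach_alpha
  report$working_correlation <- val$gee$alpha
  cut4 <- val$cutoffs[val$cutoffs$cutoff == config$cutoff, ]
  report$cutoff <- config$cutoff
  report$sensitivity_at_cutoff <- cut4$sensitivity
  report$specificity_at_cutoff <- cut4$specificity

  report$na_policy <- config$na_policy
  report$warnings <- warnings_log
  report$timings_sec <- timings
  if (!is.null(truth_sorting)) report$sorting_truth_clusters <- max(truth_sorting$cluster)
  if (!is.null(truth_patients)) report$patient_truth_intercept <- truth_patients$intercept
  class(report) <- "dtpd_run_report"
  write_report(report, file.path(out_dir, "report.json"))
  report
}

#' @export
print.dtpd_run_report <- function(x, ...) {
  cat("<dtpd_run_report>\n")
  cat(sprintf("  items/sorters: %d / %d, stress = %.3f\n",
              x$n_items, x$n_sorters, x$stress))
  cat(sprintf("  reliability mean r = %.3f (Spearman-Brown %.3f)\n",
              x$reliability$mean_r, x$reliability$sb_corrected))
  cat(sprintf("  patients: %d, AUC = %.3f (%.3f-%.3f), alpha = %.3f\n",
              x$n_patients, x$auc, x$auc_ci[1], x$auc_ci[2], x$cronbach_alpha))
  cat(sprintf("  sens/spec at cutoff %d: %.3f / %.3f\n",
              x$cutoff, x$sensitivity_at_cutoff, x$specificity_at_cutoff))
  if (length(x$warnings) > 0) cat(sprintf("  %d warning(s) logged\n", length(x$warnings)))
  invisible(x)
}
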