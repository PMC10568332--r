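# End-to-end orchestration: generator -> cohort -> covariates -> diagnostics
# -> targeted estimation, plus the replicate-level calibration harness.

#' Assemble a run configuration
#'
#' A fully serializable description of one analysis run: either a generator
#' configuration or a directory of event-table CSVs, the analysis window and
#' episode grouping, stratum selection, learner profile, folds, seeds,
#' clipping bounds and variance mode. A persisted configuration re-runs to
#' identical outputs.
#'
#' @param generator A [generator_config()], or `NULL` when reading tables.
#' @param tables_dir Directory of event-table CSVs (used when `generator`
#'   is `NULL`).
#' @param window Analysis window; `NULL` uses the generator's study window.
#' @param episode_window_days Episode grouping window (default 7).
#' @param drop_mixed Exclude mixed-mode episodes (sensitivity analysis).
#' @param stratum `"both"`, `"adult"`, `"child"` or `"all"`.
#' @param learner_profile Learner profile name (see [learner_library()]).
#' @param K Cross-validation folds.
#' @param seed Root analysis seed.
#' @param g_bounds Propensity clipping bounds.
#' @param variance Influence-curve variance mode.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(), tables_dir = NULL,
                       window = NULL, episode_window_days = 7,
                       drop_mixed = FALSE, stratum = "both",
                       learner_profile = "fast", K = 10, seed = 1,
                       g_bounds = c(0.005, 0.995), variance = "individual") {
  if (is.null(generator) && is.null(tables_dir)) {
    abort("supply a generator config or a tables directory", class = "teletmle_config_error")
  }
  structure(
    list(generator = generator, tables_dir = tables_dir, window = window,
         episode_window_days = episode_window_days, drop_mixed = drop_mixed,
         stratum = stratum, learner_profile = learner_profile, K = K,
         seed = as.integer(seed), g_bounds = g_bounds, variance = variance),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "teletmle_pipeline_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the event tables, builds the episode cohort with its
#' attrition flow, engineers covariates, produces the descriptive summary
#' table, covariate-balance report and positivity diagnostics, and runs the
#' targeted estimation per stratum. When `out_dir` is given, every artifact
#' is written there (tables as CSV, results as JSON, plus a manifest).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `tables`, `cohort`, `covariates`,
#'   `summary`, `balance`, `analysis`, and `manifest`.
#' @export
run_all <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  tables <- stage("generate", {
    if (!is.null(config$generator)) generate_study(config$generator)
    else read_event_tables(config$tables_dir)
  })
  cohort <- stage("cohort", build_cohort(
    tables, window = config$window,
    episode_window_days = config$episode_window_days,
    drop_mixed = config$drop_mixed
  ))
  covariates <- stage("covariates", build_covariates(cohort, tables))
  ep <- cohort$episodes
  summary_tbl <- stage("summary", summary_table(
    dplyr::left_join(ep, covariates, by = c("episode_id", "patient_id", "practice_id", "stratum")),
    vars = c("Y", "sex", "imd_quintile", "ethnicity", "age", "clinician_role"),
    by = "A"
  ))
  balance <- stage("balance", balance_report(
    dplyr::left_join(ep, dplyr::select(covariates, -"sex", -"clinician_role"),
                     by = c("episode_id", "patient_id", "practice_id", "stratum")),
    arm = "A",
    vars = c("age", "sex", "imd_quintile", "subtype_urti", "subtype_lrti",
             "subtype_otitis_media", "urban_flag", "infection_rate",
             "practice_abx_rate_10k", "cons_all_30d")
  ))
  analysis <- stage("estimate", run_tmle(
    cohort, covariates, stratum = config$stratum,
    learner_profile = config$learner_profile, K = config$K,
    seed = config$seed, g_bounds = config$g_bounds,
    variance = config$variance
  ))
  manifest <- list(
    seed = config$seed, K = config$K, stratum = config$stratum,
    learner_profile = config$learner_profile,
    drop_mixed = config$drop_mixed,
    attrition = as.list(setNames(cohort$attrition$n, cohort$attrition$stage)),
    analysis = analysis$manifest
  )
  result <- list(tables = tables, cohort = cohort, covariates = covariates,
                 summary = summary_tbl, balance = balance,
                 analysis = analysis, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ep, file.path(out_dir, "episodes.csv"), row.names = FALSE)
    utils::write.csv(covariates, file.path(out_dir, "covariates.csv"), row.names = FALSE)
    jsonlite::write_json(attr(covariates, "schema"),
                         file.path(out_dir, "covariate_schema.json"),
                         auto_unbox = TRUE, null = "null")
    utils::write.csv(summary_tbl, file.path(out_dir, "summary_table.csv"), row.names = FALSE)
    utils::write.csv(balance, file.path(out_dir, "balance.csv"), row.names = FALSE)
    jsonlite::write_json(
      setNames(as.list(cohort$attrition$n), cohort$attrition$stage),
      file.path(out_dir, "attrition.json"), auto_unbox = TRUE
    )
    jsonlite::write_json(
      lapply(analysis$strata, function(s) {
        list(estimates = s$tmle$estimates, eps = s$tmle$eps, score = s$tmle$score,
             n = s$n, n_remote = s$n_remote,
             positivity = list(min = s$positivity$min, max = s$positivity$max,
                               share_outside = s$positivity$share_outside),
             superlearner = list(
               g_weights = as.list(s$g_fit$alpha),
               q_weights = as.list(s$q_fit$alpha),
               fold_map = s$folds$cluster_fold,
               K = s$folds$K, seed = s$folds$seed
             ))
      }),
      file.path(out_dir, "estimates.json"), auto_unbox = TRUE, digits = NA
    )
    writeLines(report_text(analysis), file.path(out_dir, "report.txt"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(result)
}

#' Replicate-level calibration of the estimator against the generator truth
#'
#' Repeats generate -> build cohort -> engineer covariates -> targeted
#' estimation across seeded replicates and summarises bias, empirical SE,
#' mean estimated SE, and 95% CI coverage for the ATE and the log marginal
#' OR against the generator's Monte-Carlo ground truth.
#'
#' @param config A [run_config()] holding a generator configuration.
#' @param n_reps Number of replicates (>= 2).
#' @param truth Optional `truth_params`; computed from the generator when
#'   `NULL`.
#' @param stratum Stratum analysed per replicate (default `"all"`, pooled).
#' @return A `calibration` list: `reps` (per-replicate tibble) and `summary`.
#' @export
simulate_calibration <- function(config, n_reps, truth = NULL, stratum = "all") {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$generator)) {
    abort("calibration needs a generator-based config", class = "teletmle_config_error")
  }
  if (!is.numeric(n_reps) || n_reps < 2) {
    abort("n_reps must be at least 2", class = "teletmle_config_error")
  }
  if (is.null(truth)) {
    truth <- true_marginal_effects(config$generator, n_mc = 2e5, stratum = stratum)
  }
  base_seed <- derive_seed(config$seed, "reps")
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    gen <- config$generator
    gen$seed <- (base_seed + 7L * r) %% 2147483629L
    tabs <- generate_study(gen)
    coh <- build_cohort(tabs, drop_mixed = config$drop_mixed,
                        episode_window_days = config$episode_window_days)
    W <- build_covariates(coh, tabs)
    an <- run_tmle(coh, W, stratum = stratum,
                   learner_profile = config$learner_profile,
                   K = config$K, seed = gen$seed,
                   g_bounds = config$g_bounds, variance = config$variance)
    f <- an$strata[[stratum]]$tmle
    orr <- f$estimates[f$estimates$parameter == "or", ]
    tibble::tibble(
      rep = r, n = f$n, ate = f$ate, se_ate = f$se_ate,
      ate_lo = f$ate - 1.96 * f$se_ate, ate_hi = f$ate + 1.96 * f$se_ate,
      or = f$or, or_lo = orr$ci_lower, or_hi = orr$ci_upper
    )
  })
  true_ate <- truth$true_ate
  true_log_or <- log(truth$true_or)
  summary <- tibble::tibble(
    parameter = c("ate", "log_or"),
    truth = c(true_ate, true_log_or),
    mean_estimate = c(mean(reps$ate), mean(log(reps$or))),
    bias = c(mean(reps$ate) - true_ate, mean(log(reps$or)) - true_log_or),
    empirical_se = c(sd(reps$ate), sd(log(reps$or))),
    mean_estimated_se = c(mean(reps$se_ate), NA_real_),
    coverage = c(
      mean(reps$ate_lo <= true_ate & true_ate <= reps$ate_hi),
      mean(log(reps$or_lo) <= true_log_or & true_log_or <= log(reps$or_hi))
    )
  )
  structure(list(reps = reps, summary = summary, truth = truth, n_reps = n_reps),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration>", x$n_reps, "replicates\n")
  print(x$summary)
  invisible(x)
}
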