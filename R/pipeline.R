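# End-to-end pipeline on a synthetic cohort: simulate -> split -> fit the
# basic model -> stepwise covariate search -> final model -> VPC ->
# PK-informed ML -> comparison table.

#' One-step-ahead individual forecasts
#'
#' For every non-censored trough, estimates the patient's random effects
#' by MAP from the troughs strictly before it (prior mode for the first)
#' and predicts the current trough.  This is the honest forecasting analogue
#' of post-hoc individual prediction, used both as the ML `IPRE` feature
#' and for like-for-like comparison of the PPK and ML stages.
#'
#' @param records a `tac_cohort`.
#' @param model a [ppk_model()] or [ppk_fit()].
#' @return numeric vector (ng/mL) named by patient id, one entry per
#'   non-censored observation.
#' @export
forecast_predictions <- function(records, model) {
  if (inherits(model, "ppk_fit")) model <- model$estimates
  out <- lapply(records, function(r) {
    use <- r$obs$censored == "none"
    if (!any(use)) return(numeric(0))
    times <- r$obs$time[use]
    setNames(vapply(times, function(tj)
      map_individual(r, model, upto_time = tj, at_times = tj)$ipre, 0),
      rep(r$patient_id, length(times)))
  })
  unlist(out)
}

#' Default pipeline configuration
#'
#' @param n_patients cohort size (127: 103 training / 24 test at the
#'   default 80/20 split).
#' @param seed master seed; every stage derives its own stream from it.
#' @param fraction training fraction.
#' @param forward,backward stepwise OFV thresholds.
#' @param n_sim VPC replicates (0 skips the VPC stage).
#' @param n_trials TPE iterations.
#' @param inner_folds,outer_folds nested-CV fold counts.
#' @param algorithms ML algorithms to run.
#' @param candidates covariate candidate set for the stepwise search.
#' @param cohort optional [cohort_config()] override.
#' @param out_dir optional directory for JSON artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_patients = 127, seed = 1, fraction = 0.8,
                            forward = 6.63, backward = 7.88,
                            n_sim = 1000, n_trials = 100,
                            inner_folds = 10, outer_folds = 10,
                            algorithms = c("xgb", "svr", "mlp"),
                            candidates = default_candidates(),
                            cohort = NULL, out_dir = NULL) {
  structure(list(n_patients = n_patients, seed = seed, fraction = fraction,
                 forward = forward, backward = backward, n_sim = n_sim,
                 n_trials = n_trials, inner_folds = inner_folds,
                 outer_folds = outer_folds, algorithms = algorithms,
                 candidates = candidates, cohort = cohort,
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_artifact <- function(obj, config, name) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  jsonlite::write_json(obj, file.path(config$out_dir, name),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes every stage in order: cohort simulation, patient-level
#' train/test split, FOCE fit of the covariate-free (basic) model,
#' forward-inclusion/backward-elimination covariate search, FOCE fit of
#' the selected final model, visual predictive check, ML feature assembly
#' (with the basic model's one-step-ahead IPRE), nested-CV TPE tuning and
#' test-set evaluation per algorithm, Shapley attribution, per-occasion
#' errors, and a comparison table of the PPK basic, PPK final and ML
#' test-set metrics.  Fully reproducible from `(config, seed)`; a stage
#' failure halts the pipeline with the stage name, keeping the artifacts
#' written so far.
#'
#' @param config a [pipeline_config()].
#' @return list with elements `cohort`, `split`, `fit_basic`, `trace`,
#'   `fit_final`, `vpc`, `features`, `ml` (per algorithm: tuned model,
#'   test report, attribution, per-occasion errors), `comparison`
#'   (data frame), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cc <- config$cohort %||% cohort_config(n_patients = config$n_patients)
  cohort <- stage("simulate",
                  generate_cohort(cc, seed = sub_seed(config$seed, 1)))
  split <- stage("split",
                 split_train_test(cohort, config$fraction,
                                  seed = sub_seed(config$seed, 2)))
  fit_basic <- stage("fit_basic",
                     ppk_fit(split$train, init = ppk_preset("basic")))
  write_artifact(list(ofv = fit_basic$ofv, coef = as.list(coef(fit_basic)),
                      rse_pct = as.list(fit_basic$rse_pct),
                      converged = fit_basic$converged,
                      seed = config$seed),
                 config, "fit_basic.json")
  trace <- stage("covariate_selection",
                 stepwise_covariates(split$train, fit_basic,
                                     candidates = config$candidates,
                                     forward_threshold = config$forward,
                                     backward_threshold = config$backward))
  write_artifact(list(steps = trace$steps, retained = trace$retained,
                      seed = config$seed),
                 config, "trace.json")
  fit_final <- stage("fit_final",
                     ppk_fit(split$train, init = trace$final_model))
  write_artifact(list(ofv = fit_final$ofv, coef = as.list(coef(fit_final)),
                      rse_pct = as.list(fit_final$rse_pct),
                      converged = fit_final$converged,
                      seed = config$seed),
                 config, "fit_final.json")
  vpc_res <- NULL
  if (config$n_sim > 0) {
    vpc_res <- stage("vpc",
                     vpc(split$train, fit_final, n_replicates = config$n_sim,
                         seed = sub_seed(config$seed, 3)))
    write_artifact(list(coverage = vpc_res$coverage,
                        n_replicates = vpc_res$n_replicates,
                        bins = vpc_res$bins,
                        observed_pct = as.data.frame(vpc_res$observed_pct),
                        seed = config$seed),
                   config, "vpc.json")
  } else message("VPC stage skipped (n_sim = 0)")

  features <- stage("features", list(
    train = build_feature_table(split$train, fit_basic),
    test = build_feature_table(split$test, fit_basic)))

  ml <- list()
  for (algo in config$algorithms) {
    ml[[algo]] <- stage(paste0("ml_", algo), {
      tuned <- tune_nested_cv(features$train, algo,
                              n_trials = config$n_trials,
                              seed = sub_seed(config$seed, 10 + match(
                                algo, config$algorithms)),
                              inner_folds = config$inner_folds,
                              outer_folds = config$outer_folds)
      fin <- fit_final_and_predict(features$train, features$test, tuned)
      attr_res <- feature_attribution(fin$model, features$test,
                                      seed = sub_seed(config$seed, 20))
      occ <- per_occasion_errors(fin$predictions, features$test)
      write_artifact(list(algorithm = algo,
                          hyperparameters = tuned$hyperparameters,
                          inner_cv_score = tuned$inner_cv_score,
                          test = unclass(fin$report),
                          ranking = attr_res$ranking,
                          seed = config$seed),
                     config, paste0("ml_", algo, ".json"))
      list(tuned = tuned, final = fin, attribution = attr_res,
           per_occasion = occ)
    })
  }

  comparison <- stage("comparison", {
    ppk_obs <- unlist(lapply(split$test, function(r)
      r$obs$conc[r$obs$censored == "none"]))
    rows <- list()
    for (nm in c("basic", "final")) {
      fit <- if (nm == "basic") fit_basic else fit_final
      fp <- forecast_predictions(split$test, fit)
      rows[[paste0("PPK ", nm)]] <- prediction_error_report(ppk_obs,
                                                           unname(fp))
    }
    for (algo in names(ml))
      rows[[toupper(algo)]] <- ml[[algo]]$final$report
    data.frame(model = names(rows),
               MAE = vapply(rows, `[[`, 0, "mae"),
               MAPE_pct = vapply(rows, `[[`, 0, "mape_pct"),
               RMSE = vapply(rows, `[[`, 0, "rmse"),
               R2 = vapply(rows, `[[`, 0, "r2"),
               row.names = NULL)
  })
  write_artifact(comparison, config, "comparison.json")

  list(cohort = cohort, split = split, fit_basic = fit_basic,
       trace = trace, fit_final = fit_final, vpc = vpc_res,
       features = features, ml = ml, comparison = comparison,
       config = config)
}
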