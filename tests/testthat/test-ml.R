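# Shared small fitted pieces for the ML tests.
ml_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_cohort(small_config(40), seed = 61)
      fb <- quiet_fit(coh, init = ppk_preset("basic"), estimate_se = FALSE)
      rows <- build_feature_table(coh, fb)
      cache <<- list(coh = coh, fb = fb, rows = rows)
    }
    cache
  }
})

test_that("UDOSE accumulates the dose per kilogram since the last trough", {
  rec <- toy_patient(amt = 5, days = 7, trough_pod = c(3, 6), wt = 60)
  coh <- tacppk:::as_cohort(list(rec))
  rows <- build_feature_table(coh, ppk_preset("basic"))
  # second trough: exactly 3 days of 5 mg BID = 30 mg over 60 kg
  expect_equal(rows$UDOSE[2], 30 / 60)
  # first trough: from the transplant-day first dose (6 doses by 72 h)
  expect_equal(rows$UDOSE[1], 30 / 60)
  expect_equal(rows$AMT, c(10, 10))  # daily dose in effect
})

test_that("rows with missing covariates are dropped, others kept", {
  rec <- toy_patient(trough_pod = c(3, 7, 14))
  rec$covariates$HCT[2] <- NA
  coh <- tacppk:::as_cohort(list(rec))
  expect_message(rows <- build_feature_table(coh, ppk_preset("basic")),
                 "dropped")
  expect_equal(nrow(rows), 2)
  expect_equal(rows$occasion, c(1, 3))
})

test_that("forecast IPRE ignores the current trough; post-hoc uses it", {
  fx <- ml_fixture()
  rows_fc <- fx$rows
  rows_ph <- build_feature_table(fx$coh[1:5], fx$fb, forecast = FALSE)
  sub_fc <- rows_fc[rows_fc$patient_id %in% rows_ph$patient_id, ]
  # post-hoc predictions should track the target more closely (leak)
  err_fc <- mean(abs(sub_fc$IPRE - sub_fc$target))
  err_ph <- mean(abs(rows_ph$IPRE - rows_ph$target))
  expect_lt(err_ph, err_fc)
  # the first trough's forecast uses the prior mode only
  r1 <- fx$coh[[1]]
  prior <- map_individual(r1, fx$fb$estimates, upto_time = r1$obs$time[1],
                          at_times = r1$obs$time[1])
  expect_equal(unname(prior$eta), c(0, 0))
})

test_that("nested-CV tuning is deterministic and leak-free by construction", {
  fx <- ml_fixture()
  t1 <- tune_nested_cv(fx$rows, "xgb", n_trials = 3, seed = 71,
                       inner_folds = 3, outer_folds = 3)
  t2 <- tune_nested_cv(fx$rows, "xgb", n_trials = 3, seed = 71,
                       inner_folds = 3, outer_folds = 3)
  expect_identical(t1$hyperparameters, t2$hyperparameters)
  expect_identical(t1$outer_predictions, t2$outer_predictions)
  # every patient sits in exactly one outer fold
  tab <- table(fx$rows$patient_id, t1$outer_fold)
  expect_true(all(rowSums(tab > 0) == 1))
  # single-trial search still returns a usable configuration
  t3 <- tune_nested_cv(fx$rows, "xgb", n_trials = 1, seed = 72,
                       inner_folds = 3, outer_folds = 3)
  expect_true(all(c("eta", "max_depth") %in% names(t3$hyperparameters)))
  expect_length(t3$outer_cv_metrics, 3)
  expect_error(tune_nested_cv(fx$rows, "xgb", space = list(), n_trials = 2),
               "empty")
})

test_that("a deep tree memorizes its training rows", {
  fx <- ml_fixture()
  tuned <- list(algorithm = "xgb", features = tacppk:::ML_FEATURES,
                hyperparameters = list(eta = 0.3, max_depth = 10,
                                       n_estimators = 300,
                                       min_child_weight = 0.5,
                                       subsample = 1, colsample_bytree = 1,
                                       gamma = 0, reg_lambda = 0))
  rows2 <- fx$rows
  rows2$patient_id <- paste0("c_", rows2$patient_id)
  fin <- fit_final_and_predict(fx$rows, rows2, tuned)
  expect_lt(fin$report$mae, 0.05)
  bad <- fx$rows[, setdiff(names(fx$rows), "IPRE")]
  expect_error(fit_final_and_predict(bad, rows2, tuned), "IPRE")
  expect_error(fit_final_and_predict(fx$rows, fx$rows, tuned), "share")
})

test_that("constant targets degrade gracefully in the report", {
  expect_warning(r <- prediction_error_report(rep(7, 5), rep(6, 5)),
                 "constant")
  expect_equal(r$r2, 0)
})

test_that("tree attribution is exactly additive; ignored features get none", {
  fx <- ml_fixture()
  tuned <- list(algorithm = "xgb", features = tacppk:::ML_FEATURES,
                hyperparameters = list(eta = 0.1, max_depth = 4,
                                       n_estimators = 80,
                                       min_child_weight = 1, subsample = 1,
                                       colsample_bytree = 1, gamma = 0,
                                       reg_lambda = 1))
  rows2 <- fx$rows; rows2$patient_id <- paste0("c_", rows2$patient_id)
  fin <- fit_final_and_predict(fx$rows, rows2, tuned)
  at <- feature_attribution(fin$model, rows2)
  expect_false(at$approximate)
  expect_lt(max(abs(at$base_value + rowSums(at$phi) - at$prediction)), 1e-6)
  # a feature replaced by pure noise before refitting earns ~no attribution
  rows_noise <- fx$rows
  rows_noise$ALB <- with_seed(1, runif(nrow(rows_noise)))
  fin2 <- fit_final_and_predict(rows_noise, rows2, tuned)
  at2 <- feature_attribution(fin2$model, rows2)
  rk <- at2$ranking
  expect_lt(rk$mean_abs_attribution[rk$feature == "ALB"],
            0.15 * max(rk$mean_abs_attribution))
})

test_that("sampling attribution is additive for the kernel regressor", {
  fx <- ml_fixture()
  tuned <- list(algorithm = "svr", features = tacppk:::ML_FEATURES,
                hyperparameters = list(cost = 5, gamma = 0.05,
                                       epsilon = 0.1))
  rows2 <- fx$rows; rows2$patient_id <- paste0("c_", rows2$patient_id)
  fin <- fit_final_and_predict(fx$rows, rows2, tuned)
  at <- feature_attribution(fin$model, rows2[1:15, ], n_samples = 10)
  expect_true(at$approximate)
  expect_lt(max(abs(at$base_value + rowSums(at$phi) - at$prediction)), 1e-8)
  expect_equal(at$prediction, unname(predict(fin$model, rows2[1:15, ])),
               tolerance = 1e-8)
})

test_that("a target planted on IPRE ranks IPRE first", {
  fx <- ml_fixture()
  rows <- fx$rows
  rows$target <- 2 + 1.5 * rows$IPRE
  tuned <- list(algorithm = "xgb", features = tacppk:::ML_FEATURES,
                hyperparameters = list(eta = 0.1, max_depth = 3,
                                       n_estimators = 150,
                                       min_child_weight = 1, subsample = 1,
                                       colsample_bytree = 1, gamma = 0,
                                       reg_lambda = 1))
  rows2 <- rows; rows2$patient_id <- paste0("c_", rows2$patient_id)
  fin <- fit_final_and_predict(rows, rows2, tuned)
  at <- feature_attribution(fin$model, rows2)
  expect_equal(at$ranking$feature[1], "IPRE")
})

test_that("per-occasion grouping pools late occasions and skips empty ones", {
  fx <- ml_fixture()
  rows <- fx$rows
  perfect <- per_occasion_errors(rows$target, rows)
  expect_true(all(vapply(perfect, `[[`, 0, "mpe_pct") == 0))
  expect_true("7+" %in% names(perfect))
  one <- rows[rows$occasion == 2, ]
  grp <- per_occasion_errors(one$IPRE, one)
  expect_equal(names(grp), "2")
  expect_match(attr(grp, "note"), "empty")
})
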