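# PK-informed machine-learning stage: feature assembly from the
# covariate-free population model, nested patient-grouped cross-validation
# with TPE hyperparameter search, final evaluation, Shapley attribution
# and per-occasion error analysis.

ML_FEATURES <- c("WT", "AMT", "POD", "RBC", "HCT", "DBIL", "BUN", "CLCR",
                 "ALB", "CYP3A5", "COMED_CA", "COMED_PPI", "COMED_VORI",
                 "UDOSE", "IPRE")

#' Assemble the machine-learning feature table
#'
#' One row per non-censored trough: the covariate panel of the occasion,
#' `AMT` (the daily dose in effect at the trough, mg), `UDOSE` (cumulative
#' dose per kg body weight administered since the previous trough sample;
#' for the first trough, since the first dose), and `IPRE`, the individual
#' prediction of the covariate-free (basic) population model.  By default
#' `IPRE` is a one-step-ahead forecast: the patient's random effects are
#' estimated by MAP from troughs strictly before the current one only, so
#' the feature never looks at the value it predicts.  The same-time
#' (post-hoc) variant is available via `forecast = FALSE` for comparison.
#'
#' @param records a `tac_cohort`.
#' @param basic_fit a [ppk_fit()] of the covariate-free model (or a
#'   [ppk_model()]).
#' @param forecast logical; `FALSE` lets the MAP step see the current
#'   trough (leaky, for comparison only).
#' @return data frame of class `tac_features`: `patient_id`, `occasion`,
#'   the features, and `target` (observed trough, ng/mL).  Rows with a
#'   missing covariate are dropped with a message.
#' @export
build_feature_table <- function(records, basic_fit, forecast = TRUE) {
  model <- if (inherits(basic_fit, "ppk_fit")) basic_fit$estimates
           else basic_fit
  stopifnot(inherits(model, "ppk_model"))
  if (length(model$beta))
    warning("IPRE features are meant to come from the covariate-free ",
            "(basic) model; the supplied model has covariates")
  preps <- prepare_cohort(records)
  rows <- lapply(seq_along(records), function(ri) {
    r <- records[[ri]]
    use <- r$obs$censored == "none"
    if (!any(use)) return(NULL)
    o <- r$obs[use, , drop = FALSE]
    cv <- r$covariates[use, , drop = FALSE]
    times <- o$time
    ipre <- forecast_subject(preps[[ri]], model, forecast)
    prev <- c(-Inf, head(times, -1))
    udose <- vapply(seq_along(times), function(j)
      sum(r$doses$amt[r$doses$time >= prev[j] &
                        r$doses$time < times[j]]), 0) / cv$WT
    amt_daily <- 2 * vapply(times, function(tj) {
      di <- which(r$doses$time <= tj)
      r$doses$amt[di[length(di)]]
    }, 0)
    out <- data.frame(patient_id = r$patient_id, occasion = o$occasion,
                      WT = cv$WT, AMT = amt_daily, POD = o$pod,
                      RBC = cv$RBC, HCT = cv$HCT, DBIL = cv$DBIL,
                      BUN = cv$BUN, CLCR = cv$CLCR, ALB = cv$ALB,
                      CYP3A5 = cv$CYP3A5, COMED_CA = cv$COMED_CA,
                      COMED_PPI = cv$COMED_PPI, COMED_VORI = cv$COMED_VORI,
                      UDOSE = udose, IPRE = ipre, target = o$conc)
    out
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  keep <- stats::complete.cases(df[, c(ML_FEATURES, "target")])
  if (any(!keep))
    message(sum(!keep), " row(s) dropped for missing covariates")
  df <- df[keep, , drop = FALSE]
  class(df) <- c("tac_features", "data.frame")
  df
}

# ---- algorithm wrappers ------------------------------------------------

#' Default hyperparameter search spaces
#'
#' Per-algorithm parameter ranges searched by [tune_nested_cv()]: each
#' entry is `list(type, lo, hi)` with `type` one of `"uniform"`,
#' `"loguniform"`, `"int"`, or `list(type = "categorical", values = ...)`.
#'
#' @param algorithm `"xgb"`, `"svr"` or `"mlp"`.
#' @return named list of parameter specifications.
#' @export
default_space <- function(algorithm) {
  switch(algorithm,
    xgb = list(
      eta = list(type = "loguniform", lo = 0.01, hi = 0.3),
      max_depth = list(type = "int", lo = 3, hi = 10),
      n_estimators = list(type = "int", lo = 50, hi = 400),
      min_child_weight = list(type = "loguniform", lo = 0.1, hi = 10),
      subsample = list(type = "uniform", lo = 0.5, hi = 1),
      colsample_bytree = list(type = "uniform", lo = 0.5, hi = 1),
      gamma = list(type = "loguniform", lo = 1e-3, hi = 10),
      reg_lambda = list(type = "loguniform", lo = 1e-2, hi = 10)),
    svr = list(
      cost = list(type = "loguniform", lo = 0.1, hi = 100),
      gamma = list(type = "loguniform", lo = 1e-3, hi = 1),
      epsilon = list(type = "loguniform", lo = 0.01, hi = 1)),
    mlp = list(
      size = list(type = "int", lo = 4, hi = 64),
      decay = list(type = "loguniform", lo = 1e-5, hi = 1e-1)),
    stop("unknown algorithm: ", algorithm))
}

fit_algorithm <- function(algorithm, hp, X, y, features = colnames(X)) {
  X <- as.matrix(X)
  if (algorithm == "xgb") {
    bs <- mean(y)
    booster <- xgboost::xgb.train(
      params = list(eta = hp$eta, max_depth = hp$max_depth,
                    min_child_weight = hp$min_child_weight,
                    subsample = hp$subsample,
                    colsample_bytree = hp$colsample_bytree,
                    gamma = hp$gamma, lambda = hp$reg_lambda,
                    base_score = bs, objective = "reg:squarederror",
                    nthread = 1, seed = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = hp$n_estimators, verbose = 0)
    structure(list(algorithm = "xgb", booster = booster, base_score = bs,
                   features = features, hp = hp), class = "tac_ml_model")
  } else {
    ctr <- colMeans(X); scl <- pmax(apply(X, 2, sd), 1e-8)
    Xs <- scale(X, ctr, scl)
    if (algorithm == "svr") {
      fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                        cost = hp$cost, gamma = hp$gamma,
                        epsilon = hp$epsilon, scale = FALSE)
    } else {
      my <- mean(y); sy <- max(sd(y), 1e-8)
      fit <- nnet::nnet(Xs, (y - my) / sy, size = hp$size,
                        decay = hp$decay, linout = TRUE, maxit = 500,
                        MaxNWts = 10000, trace = FALSE)
      attr(fit, "y_center") <- my; attr(fit, "y_scale") <- sy
    }
    structure(list(algorithm = algorithm, fit = fit, center = ctr,
                   scale = scl, features = features, hp = hp),
              class = "tac_ml_model")
  }
}

#' @export
predict.tac_ml_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  if (object$algorithm == "xgb") {
    predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1))
  } else {
    Xs <- scale(X, object$center, object$scale)
    if (object$algorithm == "svr") as.vector(predict(object$fit, Xs))
    else as.vector(predict(object$fit, Xs)) * attr(object$fit, "y_scale") +
      attr(object$fit, "y_center")
  }
}

# patient-grouped fold assignment
group_folds <- function(patient_id, k) {
  ids <- unique(patient_id)
  if (length(ids) < k) k <- length(ids)
  fold_of <- setNames(rep(seq_len(k), length.out = length(ids)),
                      sample(ids))
  unname(fold_of[as.character(patient_id)])
}

cv_objective <- function(rows, algorithm, hp, folds, features) {
  maes <- mapes <- c()
  for (k in sort(unique(folds))) {
    tr <- rows[folds != k, , drop = FALSE]
    te <- rows[folds == k, , drop = FALSE]
    if (!nrow(te)) next
    m <- fit_algorithm(algorithm, hp, tr[, features], tr$target, features)
    p <- predict(m, te)
    maes <- c(maes, mean(abs(p - te$target)))
    mapes <- c(mapes, 100 * mean(abs(p - te$target) / te$target))
  }
  # the tuning objective: mean fold MAE (ng/mL) plus mean fold MAPE (%)
  mean(maes) + mean(mapes)
}

tpe_search <- function(rows, algorithm, space, n_trials, folds, features) {
  xs <- list(); ys <- numeric(0)
  for (t in seq_len(n_trials)) {
    cand <- tpe_suggest(space, xs, ys)
    y <- cv_objective(rows, algorithm, cand, folds, features)
    xs[[t]] <- cand; ys[t] <- y
  }
  best <- which.min(ys)
  list(hp = xs[[best]], score = ys[best], trials = ys)
}

#' Nested cross-validated TPE tuning
#'
#' Hyperparameters are searched by a Tree-structured Parzen Estimator
#' minimising the sum of the mean fold MAE (ng/mL) and mean fold MAPE (%)
#' over an inner patient-grouped 10-fold cross-validation; an outer
#' 10-fold cross-validation (patients never shared between the inner
#' training folds and the outer assessment fold) reports unbiased metrics
#' of the whole tuned pipeline.  The returned hyperparameters come from a
#' final TPE run on all rows.
#'
#' @param rows a `tac_features` table (>= 20 patients).
#' @param algorithm `"xgb"` (gradient-boosted trees), `"svr"` (RBF
#'   epsilon-SVR) or `"mlp"` (feed-forward network).
#' @param space search space (default [default_space()] for the
#'   algorithm).
#' @param n_trials TPE iterations per search (default 100).
#' @param seed integer seed; results are deterministic given it.
#' @param inner_folds,outer_folds fold counts (default 10/10).
#' @return object of class `tac_ml_tuned`: `algorithm`, `hyperparameters`,
#'   `inner_cv_score`, `outer_cv_metrics` (one [prediction_error_report()]
#'   per outer fold), `outer_predictions`, `outer_fold`.
#' @export
tune_nested_cv <- function(rows, algorithm = c("xgb", "svr", "mlp"),
                           space = NULL, n_trials = 100, seed = 1,
                           inner_folds = 10, outer_folds = 10) {
  algorithm <- match.arg(algorithm)
  space <- space %||% default_space(algorithm)
  tpe_space_check(space)
  stopifnot(length(unique(rows$patient_id)) >= 20)
  features <- ML_FEATURES
  with_seed(seed, {
    outer <- group_folds(rows$patient_id, outer_folds)
    preds <- rep(NA_real_, nrow(rows))
    reports <- list()
    for (k in sort(unique(outer))) {
      tr <- rows[outer != k, , drop = FALSE]
      te <- rows[outer == k, , drop = FALSE]
      inner <- group_folds(tr$patient_id, inner_folds)
      sr <- tpe_search(tr, algorithm, space, n_trials, inner, features)
      m <- fit_algorithm(algorithm, sr$hp, tr[, features], tr$target,
                         features)
      p <- predict(m, te)
      preds[outer == k] <- p
      reports[[length(reports) + 1]] <- prediction_error_report(te$target, p)
    }
    inner_all <- group_folds(rows$patient_id, inner_folds)
    final <- tpe_search(rows, algorithm, space, n_trials, inner_all,
                        features)
    structure(list(algorithm = algorithm, hyperparameters = final$hp,
                   inner_cv_score = final$score,
                   outer_cv_metrics = reports,
                   outer_predictions = preds, outer_fold = outer,
                   features = features, n_trials = n_trials, seed = seed),
              class = "tac_ml_tuned")
  })
}

#' @export
print.tac_ml_tuned <- function(x, ...) {
  cat(sprintf("Tuned %s pipeline (%d TPE trials)\n", x$algorithm,
              x$n_trials))
  cat("  hyperparameters:",
      paste(names(x$hyperparameters),
            vapply(x$hyperparameters, function(v) format(v, digits = 4), ""),
            sep = "=", collapse = ", "), "\n")
  mae <- mean(vapply(x$outer_cv_metrics, `[[`, 0, "mae"))
  mape <- mean(vapply(x$outer_cv_metrics, `[[`, 0, "mape_pct"))
  cat(sprintf("  inner objective %.3f; outer-CV MAE %.3f ng/mL, MAPE %.1f%%\n",
              x$inner_cv_score, mae, mape))
  invisible(x)
}

#' Refit the tuned pipeline and evaluate on a test set
#'
#' @param rows_train,rows_test `tac_features` tables with disjoint patient
#'   sets.
#' @param tuned a [tune_nested_cv()] result (or a list with `algorithm`
#'   and `hyperparameters`).
#' @return list: `model` (the refitted pipeline), `predictions` (test
#'   predictions, ng/mL), `report` (a [prediction_error_report()]).
#' @export
fit_final_and_predict <- function(rows_train, rows_test, tuned) {
  features <- tuned$features %||% ML_FEATURES
  miss_tr <- setdiff(c(features, "target"), names(rows_train))
  miss_te <- setdiff(c(features, "target"), names(rows_test))
  if (length(miss_tr) || length(miss_te))
    stop("feature-schema mismatch; missing column(s): ",
         paste(unique(c(miss_tr, miss_te)), collapse = ", "))
  if (length(intersect(rows_train$patient_id, rows_test$patient_id)))
    stop("training and test sets share patients")
  m <- fit_algorithm(tuned$algorithm, tuned$hyperparameters,
                     rows_train[, features], rows_train$target, features)
  p <- predict(m, rows_test)
  list(model = m, predictions = p,
       report = prediction_error_report(rows_test$target, p))
}

#' Per-feature Shapley attribution
#'
#' For gradient-boosted trees the attribution is the exact tree-path
#' Shapley value computed in double precision, so per row the attributions
#' plus the base value reconstruct the (double-precision) model prediction
#' to machine accuracy.  Models without an exact algorithm (SVR, network)
#' fall back to a fixed-seed permutation-sampling approximation, flagged
#' `approximate`.
#'
#' @param model a fitted `tac_ml_model` (from [fit_final_and_predict()]'s
#'   `model` element or [tune_nested_cv()] + refit).
#' @param rows `tac_features` rows to explain.
#' @param n_samples permutation samples for the approximate backend.
#' @param seed seed for the approximate backend.
#' @return object of class `tac_attribution`: `phi` (rows x features),
#'   `base_value`, `prediction` (reconstructed), `ranking` (features by
#'   decreasing mean |attribution|), `approximate`.
#' @export
feature_attribution <- function(model, rows, n_samples = 40, seed = 1) {
  stopifnot(inherits(model, "tac_ml_model"))
  res <- if (model$algorithm == "xgb") {
    shap_tree(model, as.data.frame(rows)[, model$features, drop = FALSE])
  } else {
    shap_sampling(function(X) predict(model, X),
                  as.data.frame(rows)[, model$features, drop = FALSE],
                  n_samples = n_samples, seed = seed)
  }
  imp <- sort(colMeans(abs(res$phi)), decreasing = TRUE)
  structure(list(phi = res$phi, base_value = res$base_value,
                 prediction = res$prediction,
                 ranking = data.frame(feature = names(imp),
                                      mean_abs_attribution = unname(imp)),
                 approximate = res$approximate),
            class = "tac_attribution")
}

#' @export
print.tac_attribution <- function(x, ...) {
  cat("Shapley attribution",
      if (x$approximate) "(sampling approximation)" else "(exact, trees)",
      "\n")
  print(head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

#' @export
plot.tac_attribution <- function(x, top = 10, ...) {
  imp <- rev(head(x$ranking$mean_abs_attribution, top))
  nm <- rev(head(x$ranking$feature, top))
  op <- par(mar = c(4, 7, 2, 1)); on.exit(par(op))
  barplot(imp, names.arg = nm, horiz = TRUE, las = 1,
          xlab = "mean |attribution| (ng/mL)", ...)
  invisible(x)
}

#' Prediction errors by TDM occasion
#'
#' Groups test predictions by the trough's occasion index (1-6; later
#' occasions pooled as `"7+"`) and computes each group's error report.
#' Empty groups are omitted (recorded in the `note` attribute).
#'
#' @param predictions numeric predictions aligned with `rows`.
#' @param rows `tac_features` rows carrying `occasion` and `target`.
#' @return named list of [prediction_error_report()]s.
#' @export
per_occasion_errors <- function(predictions, rows) {
  stopifnot(length(predictions) == nrow(rows))
  grp <- ifelse(rows$occasion <= 6, as.character(rows$occasion), "7+")
  lev <- c(as.character(1:6), "7+")
  out <- list(); missing <- character(0)
  for (g in lev) {
    i <- grp == g
    if (!any(i)) { missing <- c(missing, g); next }
    out[[g]] <- prediction_error_report(rows$target[i], predictions[i])
  }
  if (length(missing))
    attr(out, "note") <- paste("empty occasion group(s):",
                               paste(missing, collapse = ", "))
  out
}
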