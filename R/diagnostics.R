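# Goodness-of-fit residuals, visual predictive check and prediction-error
# metrics for the population-PK stage.

#' Conditional weighted residuals
#'
#' FOCE-linearised residuals: per subject, the log-scale residual vector is
#' recentred by the linearisation about the conditional mode,
#' \eqn{r^* = \ln C_{obs} - \ln C_{pred}(\hat\eta) + G\hat\eta}, and
#' whitened by the Cholesky factor of the linearised marginal covariance
#' \eqn{G \Omega G^T + \sigma^2 I}, where `G` is the gradient of the
#' log-predictions in the random effects at the mode.  Under the true model
#' the result is approximately standard normal.
#'
#' @param records a `tac_cohort`.
#' @param fit a converged [ppk_fit()] (or any object with an `estimates`
#'   [ppk_model()]); the conditional modes are recomputed for `records`.
#' @return numeric vector, one value per non-censored observation, with the
#'   patient id as names.
#' @export
cwres <- function(records, fit) {
  model <- if (inherits(fit, "ppk_fit")) fit$estimates else fit
  stopifnot(inherits(model, "ppk_model"))
  prep <- prepare_cohort(records)
  out <- lapply(prep, function(p) {
    if (!length(p$lobs)) return(numeric(0))
    res <- foce_subject(p, model)
    G <- res$G
    V <- G %*% diag(unname(model$omega2), 2) %*% t(G) +
      model$sigma2 * diag(length(p$lobs))
    L <- tryCatch(chol(V), error = function(e)
      stop("singular linearised covariance for patient ", p$patient_id))
    rstar <- p$lobs - res$lnc + as.vector(G %*% res$eta)
    setNames(backsolve(L, rstar, transpose = TRUE),
             rep(p$patient_id, length(rstar)))
  })
  unlist(out)
}

# simulate one replicate of the observation vector for a prepared subject
sim_subject_once <- function(p, model, ke0) {
  n <- length(p$lobs)
  eta1 <- rnorm(1, 0, sqrt(model$omega2[["v"]]))
  eta2 <- rnorm(1, 0, sqrt(model$omega2[["cl"]]))
  res <- pk_propagate_cpp(p$ev_time, p$ev_amt, p$ev_obs,
                          ke0 * exp(eta2 - eta1), model$ka, FALSE)
  lnc <- log(1000 / model$theta_v) - eta1 + log(res[, 1])
  exp(lnc + rnorm(n, 0, sqrt(model$sigma2)))
}

#' Visual predictive check
#'
#' Simulates `n_replicates` datasets under the model and the observed
#' design (same doses, observation times and covariates; new random
#' effects per subject and residuals per observation), bins observations
#' by postoperative-day quantiles, and compares the observed 5th/50th/95th
#' percentile per bin with the confidence band of the same percentile
#' across simulated replicates.
#'
#' @param records a `tac_cohort` (non-censored observations are used).
#' @param model a [ppk_model()] or [ppk_fit()].
#' @param n_replicates simulation replicates (default 1000; fewer than 100
#'   triggers a warning about unstable bands).
#' @param seed integer seed; the result is deterministic given it.
#' @param bins number of POD-quantile bins (default 10).
#' @param probs percentiles to track (default 5/50/95%).
#' @param ci confidence level of the percentile bands (default 95%).
#' @return object of class `ppk_vpc`: `bins` (break table), `observed_pct`,
#'   `sim_pct_ci` (per bin and percentile: lo/median/hi across replicates),
#'   `coverage` (fraction of observed points inside the pooled simulated
#'   5th-95th band of their bin), `n_replicates`.
#' @export
vpc <- function(records, model, n_replicates = 1000, seed = 1, bins = 10,
                probs = c(0.05, 0.5, 0.95), ci = 0.95) {
  if (inherits(model, "ppk_fit")) model <- model$estimates
  stopifnot(inherits(model, "ppk_model"))
  if (n_replicates < 100)
    warning("fewer than 100 replicates: percentile bands will be unstable")
  prep <- prepare_cohort(records)
  prep <- prep[vapply(prep, function(p) length(p$lobs) > 0, TRUE)]
  ke0 <- lapply(prep, ke0_events, model = model)
  pod <- unlist(lapply(records, function(r)
    r$obs$pod[r$obs$censored == "none"]))
  obs <- unlist(lapply(records, function(r)
    r$obs$conc[r$obs$censored == "none"]))
  brk <- unique(quantile(pod, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(pod, brk, include.lowest = TRUE)
  obs_pct <- t(vapply(split(obs, bin), quantile, numeric(length(probs)),
                      probs = probs, na.rm = TRUE))
  sims <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(k)
      unlist(lapply(seq_along(prep), function(i)
        sim_subject_once(prep[[i]], model, ke0[[i]]))))
  })
  # per replicate, percentile per bin; then CI across replicates
  per_rep <- lapply(sims, function(s)
    t(vapply(split(s, bin), quantile, numeric(length(probs)),
             probs = probs, na.rm = TRUE)))
  arr <- simplify2array(per_rep)  # bins x probs x reps
  alpha <- (1 - ci) / 2
  sim_ci <- apply(arr, c(1, 2), quantile,
                  probs = c(alpha, 0.5, 1 - alpha), na.rm = TRUE)
  pooled <- split(unlist(sims), rep(bin, n_replicates))
  lo <- vapply(pooled, quantile, 0, probs = 0.05, na.rm = TRUE)
  hi <- vapply(pooled, quantile, 0, probs = 0.95, na.rm = TRUE)
  ib <- as.integer(bin)
  coverage <- mean(obs >= lo[ib] & obs <= hi[ib], na.rm = TRUE)
  structure(list(bins = data.frame(lower = head(brk, -1),
                                   upper = brk[-1],
                                   mid = (head(brk, -1) + brk[-1]) / 2,
                                   n = as.vector(table(bin))),
                 observed_pct = obs_pct, sim_pct_ci = sim_ci,
                 coverage = coverage, n_replicates = n_replicates,
                 probs = probs, ci = ci),
            class = "ppk_vpc")
}

#' @export
print.ppk_vpc <- function(x, ...) {
  cat(sprintf("Visual predictive check: %d replicates, %d POD bins\n",
              x$n_replicates, nrow(x$bins)))
  cat(sprintf("Observed points inside simulated 5th-95th band: %.1f%%\n",
              100 * x$coverage))
  invisible(x)
}

#' @export
plot.ppk_vpc <- function(x, ...) {
  b <- x$bins$mid
  ylim <- range(x$observed_pct, x$sim_pct_ci, na.rm = TRUE)
  plot(b, x$observed_pct[, 2], type = "n", ylim = ylim,
       xlab = "Postoperative day (bin midpoint)",
       ylab = "Trough concentration (ng/mL)",
       main = "Visual predictive check", ...)
  cols <- c("steelblue", "grey40", "steelblue")
  for (j in seq_along(x$probs)) {
    polygon(c(b, rev(b)), c(x$sim_pct_ci[1, , j], rev(x$sim_pct_ci[3, , j])),
            col = adjustcolor(cols[j], 0.3), border = NA)
    lines(b, x$observed_pct[, j], lty = ifelse(j == 2, 1, 2), lwd = 2)
  }
  invisible(x)
}

#' Prediction-error report
#'
#' Implements the evaluation metrics used throughout the package:
#' \deqn{MAE = \frac{1}{n}\sum |y_i - \hat y_i|, \quad
#'       MAPE = \frac{100}{n}\sum \frac{|\hat y_i - y_i|}{y_i}, \quad
#'       RMSE = \sqrt{\frac{1}{n}\sum (y_i - \hat y_i)^2},}
#' \deqn{R^2 = 1 - \frac{\sum (\hat y_i - y_i)^2}{\sum (\bar y - y_i)^2},}
#' plus the signed mean percentage error
#' \eqn{MPE = \frac{100}{n}\sum (\hat y_i - y_i)/y_i} with its
#' normal-approximation 95% CI, and the root-mean-squared relative error
#' \eqn{MRSE\% = 100\sqrt{\frac{1}{n}\sum ((\hat y_i - y_i)/y_i)^2}}.
#'
#' @param obs observed values (positive; zero observations are an error
#'   because the relative metrics are undefined).
#' @param pred predicted values, same length.
#' @return object of class `pred_error_report` (a list of the metrics and
#'   `n`).
#' @export
prediction_error_report <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) > 0)
  if (any(obs == 0)) stop("relative metrics undefined: observed value is 0")
  err <- pred - obs
  rel <- err / obs
  r2 <- {
    ssb <- sum((mean(obs) - obs)^2)
    if (ssb == 0) { warning("constant observations: R2 reported as 0"); 0 }
    else 1 - sum(err^2) / ssb
  }
  mpe <- 100 * mean(rel)
  mpe_se <- 100 * sd(rel) / sqrt(length(rel))
  structure(list(mae = mean(abs(err)),
                 mape_pct = 100 * mean(abs(rel)),
                 rmse = sqrt(mean(err^2)),
                 r2 = r2,
                 mpe_pct = mpe,
                 mpe_ci = mpe + c(-1, 1) * qnorm(0.975) * mpe_se,
                 mrse_pct = 100 * sqrt(mean(rel^2)),
                 n = length(obs)),
            class = "pred_error_report")
}

#' @export
print.pred_error_report <- function(x, ...) {
  cat(sprintf(
    "n = %d: MAE %.3g ng/mL, MAPE %.3g%%, RMSE %.3g ng/mL, R2 %.3g\n",
    x$n, x$mae, x$mape_pct, x$rmse, x$r2))
  cat(sprintf("MPE %.3g%% (95%% CI %.3g%%, %.3g%%), MRSE %.3g%%\n",
              x$mpe_pct, x$mpe_ci[1], x$mpe_ci[2], x$mrse_pct))
  invisible(x)
}
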