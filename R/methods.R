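# S3 methods for fitted population models.

#' @export
print.ppk_fit <- function(x, ...) {
  cat("Population PK fit (FOCE)\n")
  cat(sprintf("  %d patients, %d observations; OFV %.3f; %s\n",
              nrow(x$ebes), length(x$ipre), x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  print(x$estimates)
  invisible(x)
}

#' @export
coef.ppk_fit <- function(object, ...) {
  est <- object$estimates
  c(theta_v = est$theta_v, theta_cl = est$theta_cl,
    if (length(est$beta)) setNames(unlist(est$beta),
                                   paste0("beta_", names(est$beta))),
    omega2_v = unname(est$omega2["v"]), omega2_cl = unname(est$omega2["cl"]),
    sigma2 = est$sigma2)
}

#' @export
summary.ppk_fit <- function(object, ...) {
  est <- object$estimates
  nat <- c(est$theta_v, est$theta_cl, unlist(est$beta),
           est$omega2, est$sigma2)
  tab <- data.frame(estimate = nat,
                    rse_pct = if (is.null(object$rse_pct)) NA
                              else unname(object$rse_pct),
                    row.names = param_names(object$init))
  # variability rows on the reporting scale (CV% / SD%) with delta-method RSE
  k <- length(est$beta)
  rep_tab <- data.frame(
    value = c(100 * sqrt(est$omega2[["v"]]), 100 * sqrt(est$omega2[["cl"]]),
              100 * sqrt(est$sigma2)),
    rse_pct = if (is.null(object$rse_pct)) rep(NA, 3)
              else unname(object$rse_pct[3:5 + k]) / 2,
    row.names = c("IIV V/F (CV%)", "IIV CL/F (CV%)", "residual SD (%)"))
  out <- list(parameters = tab, variability = rep_tab, ofv = object$ofv,
              converged = object$converged, n_patients = nrow(object$ebes),
              n_obs = length(object$ipre))
  class(out) <- "summary.ppk_fit"
  out
}

#' @export
print.summary.ppk_fit <- function(x, ...) {
  cat(sprintf("FOCE fit: %d patients, %d observations, OFV %.3f (%s)\n\n",
              x$n_patients, x$n_obs, x$ofv,
              if (x$converged) "converged" else "not converged"))
  print(round(x$parameters, 4))
  cat("\nVariability (reporting scale):\n")
  print(round(x$variability, 1))
  invisible(x)
}

#' Predictions from a fitted population model
#'
#' `type = "ipre"` returns individual (conditional-mode) predictions,
#' re-estimating each patient's empirical-Bayes random effects from their
#' own observations; `type = "pred"` returns population predictions at
#' zero random effects.
#'
#' @param object a [ppk_fit()].
#' @param newdata a `tac_cohort`; defaults to the training data.
#' @param type `"ipre"` or `"pred"`.
#' @param ... unused.
#' @return numeric vector, one prediction (ng/mL) per non-censored
#'   observation, named by patient id.
#' @export
predict.ppk_fit <- function(object, newdata = NULL, type = c("ipre", "pred"),
                            ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    v <- if (type == "ipre") object$ipre else object$pred
    return(setNames(v, object$obs_patient))
  }
  model <- object$estimates
  prep <- prepare_cohort(newdata)
  out <- lapply(prep, function(p) {
    if (!length(p$lobs)) return(numeric(0))
    res <- if (type == "ipre") foce_subject(p, model)
           else foce_subject_cpp(p$cev_time, p$cev_amt, p$cev_obs,
                                 p$cev_n, p$cev_tau,
                                 ke0_cevents(p, model), model$ka,
                                 log(1000 / model$theta_v), p$lobs,
                                 model$sigma2, c(0, 0), c(0, 0), 0L)
    setNames(exp(res$lnc), rep(p$patient_id, length(res$lnc)))
  })
  unlist(out)
}

#' @export
residuals.ppk_fit <- function(object, type = c("cwres", "iwres"), ...) {
  type <- match.arg(type)
  if (type == "cwres") return(cwres(object$data, object))
  (log(unlist(lapply(object$data, function(r)
    r$obs$conc[r$obs$censored == "none"]))) - log(object$ipre)) /
    sqrt(object$estimates$sigma2)
}

#' Simulate replicate datasets from a fitted model
#'
#' Resimulates every non-censored observation under the fitted model and
#' the observed design (doses, times, covariates), drawing new random
#' effects per subject and residuals per observation.
#'
#' @param object a [ppk_fit()].
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` numeric vectors (simulated ng/mL, one entry per
#'   non-censored observation, ordered as `predict(object)`).
#' @export
simulate.ppk_fit <- function(object, nsim = 1, seed = 1, ...) {
  model <- object$estimates
  prep <- prepare_cohort(object$data)
  prep <- prep[vapply(prep, function(p) length(p$lobs) > 0, TRUE)]
  ke0 <- lapply(prep, ke0_events, model = model)
  with_seed(seed, lapply(seq_len(nsim), function(k)
    unlist(lapply(seq_along(prep), function(i)
      sim_subject_once(prep[[i]], model, ke0[[i]])))))
}

#' Goodness-of-fit panels for a fitted population model
#'
#' Four panels: observed vs population predictions, observed vs individual
#' predictions, conditional weighted residuals vs population prediction
#' and vs time.
#'
#' @param x a [ppk_fit()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.ppk_fit <- function(x, ...) {
  obs <- unlist(lapply(x$data, function(r)
    r$obs$conc[r$obs$censored == "none"]))
  tt <- unlist(lapply(x$data, function(r)
    r$obs$time[r$obs$censored == "none"]))
  cw <- residuals(x, "cwres")
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  lim <- range(c(obs, x$pred, x$ipre))
  plot(x$pred, obs, xlab = "PRED (ng/mL)", ylab = "Observed (ng/mL)",
       xlim = lim, ylim = lim, pch = 16, col = adjustcolor("grey20", .5), ...)
  abline(0, 1, col = "red3")
  plot(x$ipre, obs, xlab = "IPRE (ng/mL)", ylab = "Observed (ng/mL)",
       xlim = lim, ylim = lim, pch = 16, col = adjustcolor("grey20", .5), ...)
  abline(0, 1, col = "red3")
  plot(x$pred, cw, xlab = "PRED (ng/mL)", ylab = "CWRES", pch = 16,
       col = adjustcolor("grey20", .5), ...)
  abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = "red3")
  plot(tt / 24, cw, xlab = "Time (days)", ylab = "CWRES", pch = 16,
       col = adjustcolor("grey20", .5), ...)
  abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = "red3")
  invisible(x)
}
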