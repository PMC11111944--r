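# Stepwise covariate search on CL/F by likelihood-ratio testing of the
# FOCE objective: forward inclusion at p < 0.01 (dOFV >= 6.63), backward
# elimination at p < 0.005 (dOFV >= 7.88), one covariate per step with a
# refit between steps.  Ties are broken by the larger OFV change, then by
# covariate name.  Only CL/F effects are searched: trough-only data barely
# identify V/F, so volume covariates are not supported.

#' Default covariate candidate set for the clearance model
#' @export
default_candidates <- function() {
  c("CYP3A5", "HCT", "WT", "POD", "RBC", "DBIL", "BUN", "CLCR", "ALB",
    "SEX", "COMED_CA", "COMED_PPI", "COMED_VORI")
}

#' Likelihood-ratio OFV threshold
#'
#' The change in OFV between nested models is asymptotically chi-squared;
#' the stepwise search compares each covariate's OFV change against the
#' `(1 - alpha)` quantile with `df` degrees of freedom (one per covariate
#' coefficient introduced), reported rounded to 2 decimals: 6.63 at
#' `alpha = 0.01`, 7.88 at `alpha = 0.005` (df = 1).
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return the OFV threshold, rounded to 2 decimals.
#' @export
lrt_threshold <- function(alpha, df) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must be in (0, 1)")
  if (!(is.numeric(df) && length(df) == 1 && df >= 1))
    stop("df must be >= 1")
  round(qchisq(1 - alpha, df), 2)
}

refit_with <- function(records, beta, start, control) {
  init <- ppk_model(ka = start$ka, theta_v = start$theta_v,
                    theta_cl = start$theta_cl, beta = beta,
                    omega2_v = start$omega2[["v"]],
                    omega2_cl = start$omega2[["cl"]],
                    sigma2 = start$sigma2)
  ppk_fit(records, init = init, estimate_se = FALSE, control = control)
}

#' Forward inclusion of clearance covariates
#'
#' Starting from a fitted base model, each candidate is tested by adding a
#' single exponential-linear term to CL/F and refitting; the candidate
#' with the largest OFV drop at or above the threshold is kept, and the
#' search repeats until no candidate qualifies.  A candidate whose fit
#' does not converge is skipped with a warning.
#'
#' @param records training `tac_cohort`.
#' @param base_model a [ppk_model()] (or [ppk_fit()]) to start from.
#' @param candidates covariate names to try (default
#'   [default_candidates()]).
#' @param threshold OFV-drop threshold (default 6.63 = chi-squared 0.99,
#'   df 1); inclusion uses `>=`.
#' @param control passed to [ppk_fit()].
#' @return object of class `covariate_trace`: `steps` (per tested candidate:
#'   phase, step, candidate, delta OFV, decision), `final_model` (fitted
#'   `ppk_model`), `final_fit`, `retained`.
#' @export
forward_inclusion <- function(records, base_model,
                              candidates = default_candidates(),
                              threshold = lrt_threshold(0.01, 1),
                              control = list()) {
  if (!length(candidates)) stop("candidates must be non-empty")
  cur_fit <- if (inherits(base_model, "ppk_fit")) base_model
             else ppk_fit(records, init = base_model, estimate_se = FALSE,
                          control = control)
  steps <- NULL
  step_no <- 0L
  repeat {
    step_no <- step_no + 1L
    est <- cur_fit$estimates
    remaining <- sort(setdiff(candidates, names(est$beta)))
    if (!length(remaining)) break
    dofv <- setNames(rep(NA_real_, length(remaining)), remaining)
    fits <- list()
    for (cand in remaining) {
      f <- tryCatch(
        refit_with(records, c(est$beta, setNames(0, cand)), est, control),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) {
        warning("candidate ", cand, " skipped: fit did not converge")
        next
      }
      dofv[cand] <- cur_fit$ofv - f$ofv
      fits[[cand]] <- f
    }
    qual <- !is.na(dofv) & dofv >= threshold
    best <- if (any(qual)) {
      q <- dofv[qual]
      names(q)[order(-q, names(q))][1]
    } else NA_character_
    steps <- rbind(steps, data.frame(
      phase = "forward", step = step_no, candidate = remaining,
      delta_ofv = unname(dofv),
      decision = ifelse(remaining %in% best, "added",
                        ifelse(is.na(dofv), "skipped", "rejected"))))
    if (is.na(best)) break
    cur_fit <- fits[[best]]
  }
  structure(list(steps = steps, final_model = cur_fit$estimates,
                 final_fit = cur_fit,
                 retained = names(cur_fit$estimates$beta),
                 threshold = threshold),
            class = "covariate_trace")
}

#' Backward elimination of clearance covariates
#'
#' Starting from a fitted full model, each retained covariate is removed
#' in turn (its coefficient fixed to zero, the rest refitted); the
#' covariate whose removal raises the OFV the least is eliminated while
#' that rise is below the threshold.  A covariate whose removal raises the
#' OFV by at least the threshold (`>=`) is retained.
#'
#' @param records training `tac_cohort`.
#' @param full_model a [ppk_model()] (or [ppk_fit()]) containing the
#'   covariates to test.
#' @param threshold OFV-rise threshold (default 7.88 = chi-squared 0.995,
#'   df 1).
#' @param control passed to [ppk_fit()].
#' @return a `covariate_trace` (see [forward_inclusion()]).
#' @export
backward_elimination <- function(records, full_model,
                                 threshold = lrt_threshold(0.005, 1),
                                 control = list()) {
  cur_fit <- if (inherits(full_model, "ppk_fit")) full_model
             else ppk_fit(records, init = full_model, estimate_se = FALSE,
                          control = control)
  steps <- NULL
  step_no <- 0L
  repeat {
    step_no <- step_no + 1L
    est <- cur_fit$estimates
    retained <- sort(names(est$beta))
    if (!length(retained)) break
    rise <- setNames(rep(NA_real_, length(retained)), retained)
    fits <- list()
    for (cand in retained) {
      f <- tryCatch(
        refit_with(records, est$beta[setdiff(names(est$beta), cand)],
                   est, control),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) {
        warning("removal of ", cand, " skipped: fit did not converge")
        next
      }
      rise[cand] <- f$ofv - cur_fit$ofv
      fits[[cand]] <- f
    }
    removable <- !is.na(rise) & rise < threshold
    worst <- if (any(removable)) {
      q <- rise[removable]
      names(q)[order(q, names(q))][1]
    } else NA_character_
    steps <- rbind(steps, data.frame(
      phase = "backward", step = step_no, candidate = retained,
      delta_ofv = unname(rise),
      decision = ifelse(retained %in% worst, "removed",
                        ifelse(is.na(rise), "skipped", "retained"))))
    if (is.na(worst)) break
    cur_fit <- fits[[worst]]
  }
  structure(list(steps = steps, final_model = cur_fit$estimates,
                 final_fit = cur_fit,
                 retained = names(cur_fit$estimates$beta),
                 threshold = threshold),
            class = "covariate_trace")
}

#' Full stepwise covariate search (forward then backward)
#'
#' @inheritParams forward_inclusion
#' @param forward_threshold,backward_threshold OFV thresholds for the two
#'   phases (defaults 6.63 and 7.88).
#' @return a `covariate_trace` whose `steps` concatenates both phases.
#' @export
stepwise_covariates <- function(records, base_model,
                                candidates = default_candidates(),
                                forward_threshold = lrt_threshold(0.01, 1),
                                backward_threshold = lrt_threshold(0.005, 1),
                                control = list()) {
  fw <- forward_inclusion(records, base_model, candidates,
                          forward_threshold, control)
  bw <- backward_elimination(records, fw$final_fit, backward_threshold,
                             control)
  structure(list(steps = rbind(fw$steps, bw$steps),
                 final_model = bw$final_model, final_fit = bw$final_fit,
                 retained = bw$retained,
                 threshold = c(forward = forward_threshold,
                               backward = backward_threshold)),
            class = "covariate_trace")
}

#' @export
print.covariate_trace <- function(x, ...) {
  cat("Stepwise covariate search on CL/F\n")
  if (!is.null(x$steps)) print(x$steps, row.names = FALSE)
  cat("Retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
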