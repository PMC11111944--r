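# FOCE population fitting: marginal -2 log-likelihood by per-subject
# Laplace approximation at the conditional mode with a first-order
# expansion of the log-prediction (no interaction term is needed -- the
# residual is additive and homoscedastic on the log scale).

# Precompute per-subject event schedules for the estimation kernel.
# Covariate values for dose records are carried forward from the last
# trough panel (backward-filled before the first trough), so the
# elimination rate is piecewise constant between TDM occasions.
prepare_cohort <- function(records) {
  lapply(records, function(r) {
    use <- r$obs$censored == "none"
    o <- r$obs[use, , drop = FALSE]
    if (nrow(o) && any(o$time <= r$doses$time[1]))
      stop("patient ", r$patient_id,
           ": observation at or before the first dose")
    cv <- r$covariates[use, , drop = FALSE]
    nd <- nrow(r$doses); no <- nrow(o)
    ev_time <- c(r$doses$time, o$time)
    ev_amt <- c(r$doses$amt, rep(0, no))
    ev_obs <- c(rep(0L, nd), rep(1L, no))
    ord <- order(ev_time, ev_amt > 0)
    if (no) {
      cv <- cbind(cv, POD = o$pod)  # POD usable as a CL/F covariate
      di <- findInterval(r$doses$time, o$time)
      di[di == 0] <- 1
      X <- as.matrix(rbind(cv[di, , drop = FALSE], cv))[ord, , drop = FALSE]
    } else {
      X <- matrix(NA_real_, nd, length(COV_COLS) + 1,
                  dimnames = list(NULL, c(COV_COLS, "POD")))
    }
    p <- list(patient_id = r$patient_id,
              ev_time = ev_time[ord], ev_amt = ev_amt[ord],
              ev_obs = ev_obs[ord],
              X = X, lobs = log(o$conc), obs_time = o$time, obs_use = use)
    compress_trains(p)
  })
}

# Collapse runs of equally spaced, equal-amount dose events between
# observations into single "train" events (n doses, spacing tau) that the
# estimation kernel advances in closed form.  Covariates are constant
# within a run by construction (they only change at observation records).
compress_trains <- function(p) {
  n <- length(p$ev_time)
  keep <- logical(n); ev_n <- integer(n); ev_tau <- numeric(n)
  tt <- numeric(n)
  out <- 0L
  run_start <- -1L; run_len <- 0L; run_tau <- NA_real_
  run_amt <- NA_real_; run_t0 <- NA_real_; run_last <- NA_real_
  flush <- function() {
    if (run_len > 0L) {
      out <<- out + 1L
      keep[out] <<- TRUE
      tt[out] <<- run_t0
      ev_n[out] <<- run_len
      ev_tau[out] <<- if (run_len > 1L) run_tau else 0
      # reuse the run's first event slot for bookkeeping
      idx[out] <<- run_start
      amt[out] <<- run_amt
      obs[out] <<- 0L
    }
    run_len <<- 0L
  }
  idx <- integer(n); amt <- numeric(n); obs <- integer(n)
  for (i in seq_len(n)) {
    if (p$ev_obs[i] == 1L) {
      flush()
      out <- out + 1L
      tt[out] <- p$ev_time[i]; ev_n[out] <- 1L; ev_tau[out] <- 0
      idx[out] <- i; amt[out] <- 0; obs[out] <- 1L
      if (p$ev_amt[i] > 0) {  # dose sharing the observation record
        out <- out + 1L
        tt[out] <- p$ev_time[i]; ev_n[out] <- 1L; ev_tau[out] <- 0
        idx[out] <- i; amt[out] <- p$ev_amt[i]; obs[out] <- 0L
      }
    } else if (p$ev_amt[i] == 0) {
      # amount-less marker event (e.g. a de-flagged observation): emit as-is
      flush()
      out <- out + 1L
      tt[out] <- p$ev_time[i]; ev_n[out] <- 1L; ev_tau[out] <- 0
      idx[out] <- i; amt[out] <- 0; obs[out] <- 0L
    } else {
      a <- p$ev_amt[i]; t_i <- p$ev_time[i]
      if (run_len == 0L) {
        run_start <- i; run_len <- 1L; run_amt <- a
        run_t0 <- t_i; run_last <- t_i; run_tau <- NA_real_
      } else if (a == run_amt &&
                 (is.na(run_tau) || t_i - run_last == run_tau)) {
        if (is.na(run_tau)) run_tau <- t_i - run_last
        run_len <- run_len + 1L; run_last <- t_i
      } else {
        flush()
        run_start <- i; run_len <- 1L; run_amt <- a
        run_t0 <- t_i; run_last <- t_i; run_tau <- NA_real_
      }
    }
  }
  flush()
  sel <- seq_len(out)
  p$cev_time <- tt[sel]
  p$cev_amt <- amt[sel]
  p$cev_obs <- obs[sel]
  p$cev_n <- ev_n[sel]
  p$cev_tau <- ev_tau[sel]
  p$cev_idx <- idx[sel]   # row of X supplying the event's covariates
  p
}

# Typical elimination rate per (raw) event row for a given model.
ke0_events <- function(prep_i, model) {
  lcl <- rep(log(model$theta_cl), length(prep_i$ev_time))
  if (length(model$beta)) {
    Xb <- prep_i$X[, names(model$beta), drop = FALSE] %*%
      unlist(model$beta)
    lcl <- lcl + as.vector(Xb)
  }
  exp(lcl) / model$theta_v
}

# As above, aligned to the compressed (train) event schedule.
ke0_cevents <- function(prep_i, model) {
  lcl <- rep(log(model$theta_cl), length(prep_i$cev_time))
  if (length(model$beta)) {
    Xb <- prep_i$X[prep_i$cev_idx, names(model$beta), drop = FALSE] %*%
      unlist(model$beta)
    lcl <- lcl + as.vector(Xb)
  }
  exp(lcl) / model$theta_v
}

# attach the covariate design columns the model's beta needs, aligned to
# the compressed (train) event schedule the estimation kernel consumes
prep_with_beta <- function(prep, beta_names) {
  lapply(prep, function(p) {
    p$Xb <- if (length(beta_names))
      p$X[p$cev_idx, beta_names, drop = FALSE]
    else matrix(0, length(p$cev_time), 0)
    p
  })
}

cohort_ofv <- function(prep_ptr, model, maxit = 60, gtol = 1e-7) {
  foce_cohort_ptr_cpp(prep_ptr, as.numeric(unlist(model$beta)),
                      log(model$theta_cl), model$theta_v, model$ka,
                      model$sigma2, unname(model$omega2), maxit, gtol)
}

foce_subject <- function(prep_i, model, eta_start = c(0, 0), maxit = 60,
                         gtol = 1e-7) {
  res <- foce_subject_cpp(prep_i$cev_time, prep_i$cev_amt, prep_i$cev_obs,
                          prep_i$cev_n, prep_i$cev_tau,
                          ke0_cevents(prep_i, model), model$ka,
                          log(1000 / model$theta_v), prep_i$lobs,
                          model$sigma2, unname(model$omega2),
                          eta_start, maxit, gtol)
  if (!isTRUE(res$ok))
    stop("non-finite prediction for patient ", prep_i$patient_id,
         " (first observation at t = ",
         if (length(prep_i$obs_time)) prep_i$obs_time[1] else NA, " h)")
  res
}

# One-step-ahead (or post-hoc) individual predictions for one prepared
# subject: the conditional mode from the troughs before each observation
# (all troughs when forecast = FALSE), evaluated at that observation.
forecast_subject <- function(prep_i, model, forecast = TRUE) {
  k <- length(prep_i$lobs)
  if (!k) return(numeric(0))
  if (!forecast) return(exp(foce_subject(prep_i, model)$lnc))
  cobs <- which(prep_i$cev_obs == 1)
  out <- numeric(k)
  for (j in seq_len(k)) {
    eta_j <- if (j == 1) c(0, 0) else {
      pj <- prep_i
      pj$cev_obs[cobs[j:k]] <- 0L
      pj$lobs <- prep_i$lobs[seq_len(j - 1)]
      foce_subject(pj, model)$eta
    }
    ev <- foce_subject_cpp(prep_i$cev_time, prep_i$cev_amt,
                           prep_i$cev_obs, prep_i$cev_n, prep_i$cev_tau,
                           ke0_cevents(prep_i, model), model$ka,
                           log(1000 / model$theta_v), prep_i$lobs,
                           model$sigma2, unname(model$omega2), eta_j, 0L)
    out[j] <- exp(ev$lnc[j])
  }
  out
}

#' FOCE marginal objective function value
#'
#' Computes the population objective function value (OFV): the sum over
#' subjects of minus twice the log of the Laplace-approximate marginal
#' likelihood, with the integrand expanded to first order about each
#' subject's conditional mode of the random effects (FOCE).  Observations
#' enter on the log-concentration scale with additive residual variance
#' `sigma2`.  The value is deterministic given data and model, additive
#' over subjects, and approaches the fixed-effects Gaussian -2
#' log-likelihood as the random-effect variances shrink to zero.
#'
#' @param records a `tac_cohort`; every record must have at least one
#'   non-censored observation.
#' @param model a [ppk_model()] at which to evaluate the objective.
#' @return the OFV (scalar); per-subject contributions and conditional
#'   modes are attached as attributes `"by_subject"` and `"eta"`.
#' @export
objective_function <- function(records, model) {
  prep <- prepare_cohort(records)
  nobs <- vapply(prep, function(p) length(p$lobs), 0L)
  if (any(nobs == 0))
    stop("patient(s) without usable observations: ",
         paste(vapply(prep[nobs == 0], `[[`, "", "patient_id"),
               collapse = ", "))
  if (any(model$omega2 < 0)) stop("singular Omega: negative variance")
  if (model$sigma2 <= 0)
    stop("estimation requires a positive residual variance")
  prepb <- prep_with_beta(prep, names(model$beta))
  res <- cohort_ofv(foce_prepare_cpp(prepb), model)
  if (!isTRUE(res$ok)) {
    i <- res$bad
    stop("non-finite prediction for patient ", prep[[i]]$patient_id,
         " (first observation at t = ", prep[[i]]$obs_time[1], " h)")
  }
  structure(res$ofv, by_subject = res$contrib, eta = res$eta)
}

# parameter packing: p = (log th_v, log th_cl, beta..., log w2v, log w2cl,
# log s2); beta on its natural scale, scaled inside the optimizer.
pack_model <- function(model) {
  c(log(model$theta_v), log(model$theta_cl), unlist(model$beta),
    log(pmax(model$omega2, 1e-10)), log(model$sigma2))
}

unpack_model <- function(p, template) {
  k <- length(template$beta)
  beta <- if (k) setNames(p[2 + seq_len(k)], names(template$beta))
          else numeric(0)
  ppk_model(ka = template$ka, theta_v = exp(p[1]), theta_cl = exp(p[2]),
            beta = beta, omega2_v = exp(p[3 + k]), omega2_cl = exp(p[4 + k]),
            sigma2 = exp(p[5 + k]))
}

param_names <- function(template) {
  c("theta_v", "theta_cl",
    if (length(template$beta)) paste0("beta_", names(template$beta)),
    "omega2_v", "omega2_cl", "sigma2")
}

#' Fit the population model by FOCE
#'
#' Minimises [objective_function()] over the population parameters (typical
#' V/F and CL/F, covariate coefficients, random-effect variances, residual
#' variance) with `ka` held fixed and positivity enforced by log
#' parameterisation.  Standard errors come from the central-difference
#' Hessian of the OFV at the optimum (`RSE% = 100 SE / |estimate|`).
#'
#' @param records training `tac_cohort`; patients without usable (non-
#'   censored) observations are dropped with a warning.
#' @param init a [ppk_model()] supplying both the model structure (which
#'   covariates act on CL/F) and the starting values.
#' @param estimate_se compute the Hessian-based standard errors (slowest
#'   part of a fit; selection loops switch it off).
#' @param fix character vector of parameters to hold at their `init`
#'   values instead of estimating: any of `"theta_v"`, `"theta_cl"`,
#'   `"beta_<name>"`, `"omega2_v"`, `"omega2_cl"`, `"sigma2"`.  (`ka` is
#'   always fixed.)
#' @param control list: `rel_tol` (outer relative OFV tolerance, 1e-7),
#'   `maxit` (outer iteration cap, 500), `inner_gtol` (conditional-mode
#'   gradient tolerance, 1e-7), `hess_step` (step of the central Hessian
#'   differences on the scaled optimizer coordinates, 5e-3).
#' @return an object of class `ppk_fit`: `estimates` (a `ppk_model`),
#'   `rse_pct`, `ofv`, `converged`, `ebes` (per-patient conditional modes
#'   and individual parameters), `ipre`/`pred` (individual and population
#'   predictions, ng/mL, one per non-censored observation), `vcov`.
#'   Never throws on non-convergence; inspect `converged`.
#' @seealso [map_individual()], [cwres()], [vpc()]
#' @export
ppk_fit <- function(records, init = ppk_preset("basic"), estimate_se = TRUE,
                    fix = character(0), control = list()) {
  stopifnot(inherits(init, "ppk_model"))
  ctl <- list(rel_tol = 1e-7, maxit = 500, inner_gtol = 1e-7,
              hess_step = 5e-3)
  ctl[names(control)] <- control
  prep <- prepare_cohort(records)
  nobs <- vapply(prep, function(p) length(p$lobs), 0L)
  if (any(nobs == 0)) {
    warning(sum(nobs == 0), " patient(s) without usable observations dropped")
    prep <- prep[nobs > 0]
    records <- as_cohort(unclass(records)[nobs > 0])
  }
  n <- length(prep)
  prepb <- prep_with_beta(prep, names(init$beta))
  prep_ptr <- foce_prepare_cpp(prepb)

  k <- length(init$beta)
  scale <- rep(1, 5 + k)
  if (k) {
    # bring covariate coefficients to unit optimizer scale
    sds <- vapply(names(init$beta), function(nm) {
      v <- unlist(lapply(prep, function(p) p$X[p$ev_obs == 1, nm]))
      max(sd(v), 1e-8)
    }, 0)
    scale[2 + seq_len(k)] <- 1 / sds
  }

  # conditional modes are re-searched from eta = 0 on every evaluation so
  # the objective is a pure function of the parameters (no hysteresis)
  ofv_eval <- function(p) {
    model <- unpack_model(p, init)
    res <- cohort_ofv(prep_ptr, model, gtol = ctl$inner_gtol)
    if (!isTRUE(res$ok) || !is.finite(res$ofv)) return(1e10)
    res$ofv
  }

  p0 <- pack_model(init)
  # box bounds: generous on the typical values, variance parameters kept
  # inside [1e-8, 25] so degenerate (noise-free) data stay identifiable
  lower <- c(-7, -7, rep(-Inf, k), rep(log(1e-8), 3))
  upper <- c(20, 20, rep(Inf, k), rep(log(25), 3))
  p0 <- pmin(pmax(p0, lower + 1e-9), upper - 1e-9)
  pnames <- param_names(init)
  bad_fix <- setdiff(fix, pnames)
  if (length(bad_fix))
    stop("unknown parameter(s) in 'fix': ", paste(bad_fix, collapse = ", "))
  free <- !(pnames %in% fix)
  if (!any(free)) stop("no free parameters to estimate")
  full0 <- p0
  f_box <- function(ps_free) {
    p <- full0
    p[free] <- ps_free / scale[free]
    if (any(p < lower) || any(p > upper)) return(1e10)
    ofv_eval(p)
  }
  # derivative-free simplex first (robust to the small kinks the
  # conditional-mode search induces), then a quasi-Newton polish
  nm <- if (sum(free) > 1) {
    optim(p0[free] * scale[free], f_box, method = "Nelder-Mead",
          control = list(maxit = 3 * ctl$maxit,
                         reltol = max(1e-9, ctl$rel_tol / 10)))
  } else {
    list(par = p0[free] * scale[free],
         value = f_box(p0[free] * scale[free]),
         convergence = 0, counts = c(0, 0))
  }
  opt <- nlminb(nm$par, f_box,
                lower = (lower * scale)[free], upper = (upper * scale)[free],
                control = list(rel.tol = ctl$rel_tol,
                               iter.max = min(ctl$maxit, 150),
                               eval.max = 1200))
  converged <- nm$convergence == 0 || opt$convergence == 0
  if (nm$value < opt$objective) {
    opt$par <- nm$par
    opt$objective <- nm$value
    opt$iterations <- nm$counts[1]
  }
  p_hat <- full0
  p_hat[free] <- opt$par / scale[free]
  est <- unpack_model(p_hat, init)

  # per-subject conditional modes, predictions, contributions at the optimum
  eta <- matrix(0, n, 2)
  ipre <- pred <- pid <- NULL
  for (i in seq_len(n)) {
    res <- foce_subject(prep[[i]], est)
    eta[i, ] <- res$eta
    ipre <- c(ipre, exp(res$lnc))
    res0 <- foce_subject_cpp(prep[[i]]$cev_time, prep[[i]]$cev_amt,
                             prep[[i]]$cev_obs, prep[[i]]$cev_n,
                             prep[[i]]$cev_tau,
                             ke0_cevents(prep[[i]], est),
                             est$ka, log(1000 / est$theta_v),
                             prep[[i]]$lobs, est$sigma2, c(0, 0),
                             c(0, 0), 0L)
    pred <- c(pred, exp(res0$lnc))
    pid <- c(pid, rep(prep[[i]]$patient_id, length(res$lnc)))
  }
  tvcl_i <- vapply(seq_len(n), function(i) {
    x <- prep[[i]]$X[prep[[i]]$ev_obs == 1, , drop = FALSE]
    if (length(est$beta))
      est$theta_cl * exp(sum(unlist(est$beta) * x[1, names(est$beta)]))
    else est$theta_cl
  }, 0)
  ebes <- data.frame(patient_id = vapply(prep, `[[`, "", "patient_id"),
                     eta_v = eta[, 1], eta_cl = eta[, 2],
                     v_f = est$theta_v * exp(eta[, 1]),
                     cl_f = tvcl_i * exp(eta[, 2]))

  vcov <- NULL; rse <- NULL
  if (estimate_se) {
    h <- hessian_ofv(prep_ptr, p_hat, scale, init, ctl, free)
    vcov_s <- tryCatch(2 * solve(h), error = function(e) NULL)
    if (!is.null(vcov_s)) {
      # delta method from scaled optimizer coordinates to natural scale
      nat <- c(est$theta_v, est$theta_cl, unlist(est$beta),
               est$omega2, est$sigma2)
      is_log <- rep(TRUE, length(nat))
      if (k) is_log[2 + seq_len(k)] <- FALSE
      J <- (ifelse(is_log, nat, 1) / scale)[free]
      vcov <- matrix(NA_real_, length(nat), length(nat),
                     dimnames = list(pnames, pnames))
      vcov[free, free] <- diag(J, length(J)) %*% vcov_s %*%
        diag(J, length(J))
      d <- diag(vcov)
      se <- ifelse(is.finite(d) & d > 0, sqrt(pmax(d, 0)), NA_real_)
      rse <- setNames(100 * se / abs(nat), pnames)
    }
  }

  structure(list(estimates = est, rse_pct = rse, ofv = opt$objective,
                 converged = converged, ebes = ebes,
                 ipre = ipre, pred = pred, obs_patient = pid,
                 vcov = vcov, init = init, data = records,
                 niter = opt$iterations, control = ctl),
            class = "ppk_fit")
}

# central-difference Hessian of the OFV on the scaled optimizer
# coordinates (log thetas, sd-scaled betas, log variances); conditioning
# on this scale is uniform so a single absolute step works
hessian_ofv <- function(prep_ptr, p_hat, scale, template, ctl,
                        free = rep(TRUE, length(p_hat))) {
  ps_full <- p_hat * scale
  ps0 <- ps_full[free]
  np <- length(ps0)
  f <- function(ps) {
    pp <- ps_full
    pp[free] <- ps
    m <- unpack_model(pp / scale, template)
    cohort_ofv(prep_ptr, m)$ofv
  }
  hstep <- rep(ctl$hess_step, np)
  H <- matrix(0, np, np)
  f0 <- f(ps0)
  fp <- fm <- numeric(np)
  for (i in seq_len(np)) {
    e <- rep(0, np); e[i] <- hstep[i]
    fp[i] <- f(ps0 + e); fm[i] <- f(ps0 - e)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / hstep[i]^2
  }
  for (i in seq_len(np)) for (j in seq_len(np)) if (i < j) {
    ei <- rep(0, np); ei[i] <- hstep[i]
    ej <- rep(0, np); ej[j] <- hstep[j]
    H[i, j] <- H[j, i] <-
      (f(ps0 + ei + ej) - fp[i] - fp[j] + 2 * f0 -
         fm[i] - fm[j] + f(ps0 - ei - ej)) / (2 * hstep[i] * hstep[j])
  }
  H
}

#' Empirical-Bayes (MAP) estimation for one patient
#'
#' With the population model fixed, finds the conditional mode of the
#' random effects,
#' \eqn{\hat\eta = \arg\min_\eta \sum_j (\ln C_{obs,j} - \ln C_{pred,j}(\eta))^2/\sigma^2
#'  + \eta^T \Omega^{-1} \eta,}
#' and returns the individual parameters and predictions at the
#' observation times.  A record with no usable observation returns the
#' prior mode \eqn{\hat\eta = 0} flagged `prior_only`.
#'
#' @param record a [tac_patient()].
#' @param model a fixed [ppk_model()].
#' @param upto_time if finite, only observations strictly before this time
#'   inform the mode (one-step-ahead forecasting); predictions are still
#'   returned at every requested time.
#' @param at_times times (h) at which to return individual predictions;
#'   defaults to the record's non-censored observation times.
#' @return list: `ind` (a `ppk_ind` from [individualize()]), `eta`
#'   (named), `ipre` (ng/mL at `at_times`), `prior_only`.
#' @export
map_individual <- function(record, model, upto_time = Inf, at_times = NULL) {
  stopifnot(inherits(model, "ppk_model"))
  prep <- prepare_cohort(list(record))[[1]]
  use <- prep$obs_time < upto_time
  prep_fit <- prep
  # restrict the informing observations, keep the full dose schedule
  obs_rows <- which(prep$ev_obs == 1)
  drop_obs <- obs_rows[!use]
  if (length(drop_obs)) {
    prep_fit$ev_obs[drop_obs] <- 0L
    prep_fit$lobs <- prep$lobs[use]
    prep_fit$obs_time <- prep$obs_time[use]
    prep_fit <- compress_trains(prep_fit)
  }
  res <- foce_subject(prep_fit, model)
  eta <- res$eta
  cv1 <- record$covariates[1, , drop = FALSE]
  ind <- individualize(model,
                       if (length(model$beta)) cv1[names(model$beta)]
                       else NULL,
                       eta_v = eta[1], eta_cl = eta[2])
  at <- at_times %||% prep$obs_time
  ipre <- if (length(at)) {
    pm <- prep
    # predictions at requested times under eta-hat
    ev_time <- c(pm$ev_time[pm$ev_obs == 0], at)
    ev_amt <- c(pm$ev_amt[pm$ev_obs == 0], rep(0, length(at)))
    ev_obs <- c(rep(0L, sum(pm$ev_obs == 0)), rep(1L, length(at)))
    ord <- order(ev_time, ev_amt > 0)
    Xd <- pm$X[pm$ev_obs == 0, , drop = FALSE]
    oi <- findInterval(at, prep$obs_time)
    oi[oi == 0] <- 1
    Xo <- pm$X[pm$ev_obs == 1, , drop = FALSE][oi, , drop = FALSE]
    Xall <- rbind(Xd, Xo)[ord, , drop = FALSE]
    pseudo <- list(patient_id = pm$patient_id, ev_time = ev_time[ord],
                   ev_amt = ev_amt[ord], ev_obs = ev_obs[ord], X = Xall)
    ke0 <- ke0_events(pseudo, model)
    out <- pk_propagate_cpp(pseudo$ev_time, pseudo$ev_amt, pseudo$ev_obs,
                            ke0 * exp(eta[2] - eta[1]), model$ka, FALSE)
    conc_sorted <- 1000 * out[, 1] / (model$theta_v * exp(eta[1]))
    conc <- numeric(length(at))
    conc[sort.int(at, index.return = TRUE)$ix] <- conc_sorted
    conc
  } else numeric(0)
  list(ind = ind, eta = c(eta_v = eta[1], eta_cl = eta[2]),
       ipre = ipre, prior_only = isTRUE(res$prior_only) || !length(prep_fit$lobs))
}
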