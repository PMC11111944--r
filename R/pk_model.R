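#' Population pharmacokinetic model object
#'
#' Constructs the population model for the one-compartment oral tacrolimus
#' model: fixed first-order absorption rate `ka`, typical apparent volume
#' `theta_v` (V/F, litres) and clearance `theta_cl` (CL/F, L/h), exponential
#' covariate effects on CL/F, log-normal inter-individual variability on both
#' dispositional parameters, and an additive residual on the log-concentration
#' scale.
#'
#' The model is
#' \deqn{V/F_i = \theta_V e^{\eta_{V,i}}, \quad
#'       CL/F_{ij} = \theta_{CL} \prod_k e^{\beta_k x_{kij}} \; e^{\eta_{CL,i}},}
#' \deqn{\ln C_{obs,ij} = \ln C_{pred,ij} + \varepsilon_{ij},}
#' with \eqn{\eta \sim N(0, \Omega)} (diagonal) and
#' \eqn{\varepsilon \sim N(0, \sigma^2)}.  Covariates may vary over time
#' within a patient (one panel per observation record).
#'
#' @param ka absorption rate constant (1/h); fixed, never estimated.
#' @param theta_v typical apparent volume of distribution V/F (L).
#' @param theta_cl typical apparent clearance CL/F (L/h) at covariate value 0.
#' @param beta named numeric vector of exponential covariate coefficients on
#'   CL/F; names must be covariate columns of the event table (e.g.
#'   `c(CYP3A5 = -0.348, HCT = -0.122)`).  `CYP3A5` is the *3 allele count
#'   (0, 1, 2); `HCT` is a fraction in (0, 1).
#' @param omega2_v,omega2_cl variances of the random effects on V/F and CL/F.
#' @param sigma2 variance of the residual on the log scale.
#' @return an object of class `ppk_model`.
#' @seealso [ppk_preset()], [typical_clearance()], [individualize()],
#'   [predict_concentration()]
#' @export
ppk_model <- function(ka = 3.86, theta_v = 2560, theta_cl = 70.6,
                      beta = c(CYP3A5 = -0.348, HCT = -0.122),
                      omega2_v = 0.65^2, omega2_cl = 0.23^2,
                      sigma2 = 0.356^2) {
  stopifnot(is.numeric(ka), length(ka) == 1, ka > 0,
            theta_v > 0, theta_cl > 0,
            omega2_v >= 0, omega2_cl >= 0, sigma2 >= 0)
  if (length(beta) && is.null(names(beta)))
    stop("'beta' must be a named vector of covariate coefficients")
  structure(list(ka = unname(ka), theta_v = unname(theta_v),
                 theta_cl = unname(theta_cl), beta = beta,
                 omega2 = c(v = unname(omega2_v), cl = unname(omega2_cl)),
                 sigma2 = unname(sigma2)),
            class = "ppk_model")
}

#' Shipped population model presets
#'
#' Two presets are shipped: `"final"` — the covariate model with CYP3A5
#' genotype (allele-count coding) and haematocrit on CL/F
#' (CL/F = 70.6 × e^(−0.348·CYP3A5) × e^(−0.122·HCT), V/F = 2560 L) — and
#' `"structural"` (alias `"basic"`) — the covariate-free base model
#' (CL/F = 41.1 L/h, V/F = 2620 L) whose individual predictions feed the
#' machine-learning stage.  `ka` is fixed at 3.86 1/h in both.
#'
#' Haematocrit enters as an uncentred fraction, so `theta_cl` of the final
#' preset is the extrapolated clearance of a hypothetical HCT = 0,
#' CYP3A5 *1/*1 patient.
#'
#' @param name `"final"`, `"structural"` or `"basic"`.
#' @return a [ppk_model()] object.
#' @export
ppk_preset <- function(name = c("final", "structural", "basic")) {
  name <- match.arg(name)
  switch(name,
    final = ppk_model(ka = 3.86, theta_v = 2560, theta_cl = 70.6,
                      beta = c(CYP3A5 = -0.348, HCT = -0.122),
                      omega2_v = 0.650^2, omega2_cl = 0.230^2,
                      sigma2 = 0.356^2),
    structural = ,
    basic = ppk_model(ka = 3.86, theta_v = 2620, theta_cl = 41.1,
                      beta = numeric(0),
                      omega2_v = 0.736^2, omega2_cl = 0.318^2,
                      sigma2 = 0.377^2))
}

#' @export
print.ppk_model <- function(x, ...) {
  cat("One-compartment oral population PK model\n")
  cat(sprintf("  ka       %.3g 1/h (fixed)\n", x$ka))
  cat(sprintf("  V/F      %.4g L   (omega CV %.1f%%)\n",
              x$theta_v, 100 * sqrt(x$omega2["v"])))
  cat(sprintf("  CL/F     %.4g L/h (omega CV %.1f%%)\n",
              x$theta_cl, 100 * sqrt(x$omega2["cl"])))
  if (length(x$beta))
    for (nm in names(x$beta))
      cat(sprintf("  beta[%s] %+.4g on CL/F\n", nm, x$beta[[nm]]))
  cat(sprintf("  sigma    %.3g (log-scale residual SD)\n", sqrt(x$sigma2)))
  invisible(x)
}

# Typical CL/F given a named covariate row (only covariates named in beta
# are consulted; missing ones are an error).
tvcl_row <- function(model, covs) {
  cl <- model$theta_cl
  if (length(model$beta)) {
    x <- covs[names(model$beta)]
    if (anyNA(x))
      stop("missing covariate value(s): ",
           paste(names(model$beta)[is.na(x)], collapse = ", "))
    cl <- cl * exp(sum(unlist(model$beta) * unlist(x)))
  }
  cl
}

#' Typical (population) apparent clearance for a covariate combination
#'
#' Evaluates the covariate submodel
#' \eqn{CL/F = \theta_{CL} e^{\beta_{CYP3A5}\,code} e^{\beta_{HCT}\,hct}}
#' (plus any further covariates the model carries, supplied via `...`).
#'
#' @param model a [ppk_model()].
#' @param cyp3a5_code CYP3A5 *3 allele count: 0 (*1/*1), 1 (*1/*3), 2 (*3/*3).
#' @param hct haematocrit as a fraction in (0, 1).
#' @param ... further named covariate values for models with additional
#'   coefficients.
#' @return typical CL/F in L/h.
#' @examples
#' m <- ppk_preset("final")
#' typical_clearance(m, cyp3a5_code = 1, hct = 0.29)
#' @export
typical_clearance <- function(model, cyp3a5_code = 0, hct = 0, ...) {
  stopifnot(inherits(model, "ppk_model"))
  if (!all(cyp3a5_code %in% c(0, 1, 2)))
    stop("cyp3a5_code must be 0, 1 or 2")
  if (any(hct < 0 | hct >= 1))
    stop("hct must be a fraction in [0, 1)")
  extra <- list(...)
  covs <- c(list(CYP3A5 = cyp3a5_code, HCT = hct), extra)
  need <- setdiff(names(model$beta), names(covs))
  if (length(need))
    stop("model needs covariate(s): ", paste(need, collapse = ", "))
  cl <- model$theta_cl
  for (nm in names(model$beta))
    cl <- cl * exp(model$beta[[nm]] * covs[[nm]])
  unname(cl)
}

#' Individual parameters from random effects
#'
#' Applies the exponential random-effect model
#' \eqn{V/F = \theta_V e^{\eta_V}}, \eqn{CL/F = TVCL \cdot e^{\eta_{CL}}}
#' where TVCL is the covariate-adjusted typical clearance.
#'
#' @param model a [ppk_model()].
#' @param covariates named list/vector with the covariates the model's `beta`
#'   requires (e.g. `CYP3A5`, `HCT`); ignored for a covariate-free model.
#' @param eta_v,eta_cl random effects (dimensionless).
#' @return an object of class `ppk_ind`: `eta_v`, `eta_cl`, `v_f` (L),
#'   `cl_f` (L/h) and `ke` (1/h, = cl_f/v_f).
#' @examples
#' individualize(ppk_preset("basic"), NULL, eta_v = 0, eta_cl = log(2))
#' @export
individualize <- function(model, covariates = NULL, eta_v = 0, eta_cl = 0) {
  stopifnot(inherits(model, "ppk_model"))
  covs <- if (is.null(covariates)) numeric(0) else unlist(covariates)
  tv <- if (length(model$beta)) tvcl_row(model, covs) else model$theta_cl
  v_f <- model$theta_v * exp(eta_v)
  cl_f <- tv * exp(eta_cl)
  structure(list(eta_v = eta_v, eta_cl = eta_cl,
                 v_f = v_f, cl_f = cl_f, ke = cl_f / v_f),
            class = "ppk_ind")
}

#' Predicted concentration under an arbitrary dosing history
#'
#' Superposition of one-compartment first-order absorption/elimination
#' responses over all doses administered at or before the query time:
#' \deqn{C(t) = \frac{1000}{V/F} \frac{k_a}{k_a - k_e}
#'   \sum_{d: t_d \le t} A_d (e^{-k_e (t - t_d)} - e^{-k_a (t - t_d)})}
#' with doses in mg, volume in L, concentration in ng/mL.  When
#' \eqn{|k_a - k_e|} falls below a relative epsilon the limiting form
#' \eqn{A_d k_a (t-t_d) e^{-k_a (t-t_d)}} is used instead of the
#' ill-conditioned quotient.
#'
#' @param ind a `ppk_ind` from [individualize()], or any list with `v_f` and
#'   `ke` (or `cl_f`).
#' @param ka absorption rate constant (1/h).
#' @param doses data frame with columns `time` (h) and `amt` (mg), sorted
#'   ascending in time.
#' @param t numeric vector of query times (h); each must be at or after the
#'   first dose.
#' @return concentrations in ng/mL.
#' @export
predict_concentration <- function(ind, ka, doses, t) {
  stopifnot(is.data.frame(doses), all(c("time", "amt") %in% names(doses)),
            nrow(doses) >= 1, all(doses$amt > 0), !is.unsorted(doses$time))
  v_f <- ind$v_f
  ke <- ind$ke %||% (ind$cl_f / v_f)
  stopifnot(v_f > 0, ke > 0, ka > 0)
  if (any(t < doses$time[1]))
    stop("query time precedes the first dose")
  ord <- order(t)
  ts <- t[ord]
  ev_time <- c(doses$time, ts)
  ev_amt <- c(doses$amt, rep(0, length(ts)))
  ev_obs <- c(rep(0L, nrow(doses)), rep(1L, length(ts)))
  # stable order: time, then observations before doses at equal times
  o <- order(ev_time, ev_amt > 0)
  res <- pk_propagate_cpp(ev_time[o], ev_amt[o], ev_obs[o],
                          rep(ke, length(ev_time)), ka, FALSE)
  conc <- 1000 * res[, 1] / v_f
  conc[order(ord)]
}
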