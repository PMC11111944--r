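# Independent oracles and small fixtures used across the suite.

# Plain-R superposition of one-compartment first-order responses with a
# constant elimination rate (independent of the package's event kernel).
r_superpose <- function(t, doses, ka, ke, vf) {
  vapply(t, function(tt) {
    use <- doses$time < tt | (doses$time == tt & FALSE)
    dt <- tt - doses$time[use]
    sum(doses$amt[use] * (exp(-ke * dt) - exp(-ka * dt))) *
      (1000 / vf) * ka / (ka - ke)
  }, 0)
}

# Two-ODE absorption/disposition oracle via deSolve, dosing as events.
ode_conc <- function(t, doses, ka, ke, vf) {
  ev <- data.frame(var = "Ag", time = doses$time, value = doses$amt,
                   method = "add")
  times <- sort(unique(c(0, doses$time, t)))
  out <- deSolve::lsoda(
    c(Ag = 0, Ac = 0),
    times = times,
    func = function(tt, y, p) list(c(-ka * y[1], ka * y[1] - ke * y[2])),
    parms = NULL, events = list(data = ev),
    rtol = 1e-10, atol = 1e-12)
  1000 * out[match(t, out[, "time"]), "Ac"] / vf
}

# steady-state trough of a constant BID regimen (accumulation factors)
ss_trough <- function(amt, tau, ka, ke, vf) {
  (1000 * amt / vf) * (ka / (ka - ke)) *
    (exp(-ke * tau) / (1 - exp(-ke * tau)) -
       exp(-ka * tau) / (1 - exp(-ka * tau)))
}

# a hand-built patient: BID dosing over `days` days, troughs at given PODs
toy_patient <- function(id = "T1", amt = 4, days = 14,
                        trough_pod = c(3, 7, 14), conc = NULL,
                        wt = 60, hct = 0.3, cyp = 2) {
  doses <- data.frame(time = seq(0, days * 24, by = 12), amt = amt)
  nt <- length(trough_pod)
  if (is.null(conc)) conc <- rep(8, nt)
  obs <- data.frame(time = trough_pod * 24, conc = conc, pod = trough_pod,
                    occasion = seq_len(nt), censored = "none",
                    stringsAsFactors = FALSE)
  cv <- data.frame(WT = wt, HCT = hct, RBC = 3, DBIL = 2.5, BUN = 18,
                   CLCR = 36, ALB = 34, SEX = 0, CYP3A5 = cyp,
                   COMED_CA = 1, COMED_PPI = 1, COMED_VORI = 0)
  tac_patient(id, doses, obs, cv[rep(1, nt), , drop = FALSE])
}

# simulate toy observations from a model for given random effects
toy_simulate <- function(rec, model, eta_v = 0, eta_cl = 0, sigma = 0,
                         seed = NULL) {
  cv <- rec$covariates[1, ]
  tv <- model$theta_cl
  if (length(model$beta))
    tv <- tv * exp(sum(unlist(model$beta) *
                         unlist(cv[names(model$beta)])))
  vf <- model$theta_v * exp(eta_v)
  ke <- tv * exp(eta_cl) / vf
  mu <- r_superpose(rec$obs$time, rec$doses, model$ka, ke, vf)
  eps <- if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    rnorm(length(mu), 0, sigma)
  } else 0
  rec$obs$conc <- mu * exp(eps)
  rec
}

# Adaptive 2-d Gauss-Hermite -2 log marginal likelihood (quadrature oracle;
# constant covariates per subject assumed).
agh_ofv <- function(records, model, n_nodes = 21) {
  gh <- pracma::gaussHermite(n_nodes)
  tot <- 0
  for (r in records) {
    o <- r$obs[r$obs$censored == "none", ]
    cv <- r$covariates[1, ]
    tv <- model$theta_cl
    if (length(model$beta))
      tv <- tv * exp(sum(unlist(model$beta) *
                           unlist(cv[names(model$beta)])))
    logjoint <- function(e1, e2) {
      vf <- model$theta_v * exp(e1)
      ke <- tv * exp(e2) / vf
      mu <- log(r_superpose(o$time, r$doses, model$ka, ke, vf))
      sum(dnorm(log(o$conc), mu, sqrt(model$sigma2), log = TRUE)) +
        dnorm(e1, 0, sqrt(model$omega2[["v"]]), log = TRUE) +
        dnorm(e2, 0, sqrt(model$omega2[["cl"]]), log = TRUE)
    }
    opt <- optim(c(0, 0), function(p) -logjoint(p[1], p[2]),
                 hessian = TRUE)
    A <- t(chol(solve(opt$hessian)))
    lse <- -Inf
    for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
      z <- c(gh$x[i], gh$x[j])
      eta <- opt$par + sqrt(2) * as.vector(A %*% z)
      lv <- log(gh$w[i]) + log(gh$w[j]) + sum(z^2) +
        logjoint(eta[1], eta[2])
      lse <- max(lse, lv) + log1p(exp(min(lse, lv) - max(lse, lv)))
    }
    tot <- tot - 2 * (log(2) + sum(log(diag(A))) + lse)
  }
  tot
}

quiet_fit <- function(...) suppressWarnings(ppk_fit(...))

small_config <- function(n = 30, pods = c(3, 7, 14, 30, 60, 90, 150, 210),
                         ...) {
  cohort_config(n_patients = n, schedule_pod = pods, ...)
}
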