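# Synthetic cohorts with the statistical structure of a titrated
# twice-daily tacrolimus protocol in adult renal-transplant recipients:
# weight-based starting dose, trough-guided titration to a POD-dependent
# target window, TDM panels drawn on a fixed clinical schedule, and
# trough concentrations generated from the population PK model itself.

# moment-matched lognormal
rlnorm_ms <- function(n, m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
}

rtnorm <- function(n, m, s, lower = -Inf, upper = Inf) {
  x <- rnorm(n, m, s)
  while (any(bad <- x < lower | x > upper))
    x[bad] <- rnorm(sum(bad), m, s)
  x
}

draw_cov <- function(spec, n) {
  switch(spec$dist,
         tnorm = rtnorm(n, spec$mean, spec$sd, spec$lower %||% -Inf,
                        spec$upper %||% Inf),
         lnorm = rlnorm_ms(n, spec$mean, spec$sd),
         bern = rbinom(n, 1, spec$p),
         stop("unknown covariate distribution: ", spec$dist))
}

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the training cohort of an adult Chinese renal-transplant
#' TDM series: 127 patients; CYP3A5 *1/*1, *1/*3, *3/*3 at whole-cohort
#' frequencies 9.45/33.9/56.7%; weight 63.3 +/- 12.9 kg; haematocrit with
#' marginal mean 0.29 and SD 0.056, rising with postoperative recovery;
#' protocol dosing 0.1 mg/kg/day BID (0.5 mg rounding) titrated after each
#' trough towards 10-13 ng/mL in the first month and 5-9 ng/mL thereafter;
#' assay range 2-50 ng/mL; troughs on a fixed schedule of 16 postoperative
#' days spanning 3-365.  Concentrations are generated from
#' `ppk_preset("final")`.
#'
#' @param n_patients cohort size.
#' @param genotype_freqs probabilities of CYP3A5 codes 0/1/2 (normalised).
#' @param model generative [ppk_model()].
#' @param schedule_pod postoperative days of the TDM occasions.
#' @param titration list: `up`/`down` dose multipliers applied when the
#'   trough is below/above the window, `round_mg` rounding quantum,
#'   `windows` data frame with `pod_max`, `lo`, `hi`.
#' @param covariates per-covariate sampling specs (see source).
#' @param hct list: marginal `mean`, `sd`; recovery amplitude `amp`, time
#'   constant `tau` (days), occasion-level noise `noise`.
#' @param vori_cl_effect optional multiplicative CL/F coefficient for
#'   voriconazole co-medication (exponential scale, default 0 = none);
#'   used to plant a detectable co-medication signal in selection tests.
#' @param assay_range censoring limits (ng/mL).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 127,
                          genotype_freqs = c(0.0945, 0.339, 0.567),
                          model = ppk_preset("final"),
                          schedule_pod = c(3, 5, 7, 10, 14, 21, 28, 42, 56,
                                           75, 90, 120, 150, 210, 270, 365),
                          titration = list(up = 1.25, down = 0.75,
                                           round_mg = 0.5,
                                           windows = data.frame(
                                             pod_max = c(30, Inf),
                                             lo = c(10, 5), hi = c(13, 9))),
                          covariates = list(
                            WT = list(dist = "tnorm", mean = 63.3, sd = 12.9,
                                      lower = 35, upper = 110),
                            RBC = list(dist = "tnorm", mean = 3.06, sd = 0.61,
                                       lower = 1.2, upper = 6),
                            DBIL = list(dist = "lnorm", mean = 2.58, sd = 1.17),
                            BUN = list(dist = "lnorm", mean = 18.8, sd = 10.5),
                            CLCR = list(dist = "lnorm", mean = 36, sd = 18),
                            ALB = list(dist = "tnorm", mean = 34.0, sd = 3.69,
                                       lower = 18, upper = 50),
                            SEX = list(dist = "bern", p = 0.379),
                            COMED_CA = list(dist = "bern", p = 0.786),
                            COMED_PPI = list(dist = "bern", p = 0.99),
                            COMED_VORI = list(dist = "bern", p = 0.204)),
                          hct = list(mean = 0.29, sd = 0.056, amp = 0.07,
                                     tau = 90, noise = 0.015),
                          vori_cl_effect = 0,
                          assay_range = c(2, 50)) {
  if (any(genotype_freqs < 0) || sum(genotype_freqs) <= 0)
    stop("invalid genotype frequencies")
  for (nm in names(covariates)) {
    sp <- covariates[[nm]]
    if (!is.null(sp$sd) && sp$sd < 0)
      stop("negative SD for covariate ", nm)
  }
  if (any(hct$sd < 0, hct$noise < 0)) stop("negative HCT scale parameter")
  structure(list(n_patients = n_patients,
                 genotype_freqs = genotype_freqs / sum(genotype_freqs),
                 model = model, schedule_pod = schedule_pod,
                 titration = titration, covariates = covariates,
                 hct = hct, vori_cl_effect = vori_cl_effect,
                 assay_range = assay_range),
            class = "cohort_config")
}

# haematocrit recovery trend (fraction) at a postoperative day
hct_trend <- function(pod, hct) hct$amp * (1 - exp(-pod / hct$tau))

#' Generate a synthetic cohort
#'
#' Per patient: draw the CYP3A5 genotype and covariate panel, random effects
#' \eqn{\eta \sim N(0, \Omega)}, start dosing at 0.1 mg/kg/day BID (rounded
#' to the configured quantum), then simulate each scheduled trough from the
#' generative PK model with log-normal residual error and apply the
#' titration rule to subsequent doses.  Troughs outside the assay range are
#' kept and flagged censored.  The latent per-patient truth is attached for
#' [truth_table()].
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the output is reproducible from
#'   `(config, seed)`.
#' @return a `tac_cohort` whose attribute `"truth"` holds the latent values.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  m <- config$model
  n <- config$n_patients
  pods <- sort(config$schedule_pod)
  nocc <- length(pods)
  geno <- sample(0:2, n, replace = TRUE, prob = config$genotype_freqs)
  base_cov <- lapply(config$covariates, draw_cov, n = n)

  # haematocrit components calibrated so the pooled marginal over the
  # schedule matches the configured mean/SD
  tr <- hct_trend(pods, config$hct)
  mu_b <- config$hct$mean - mean(tr)
  var_b <- max(config$hct$sd^2 - var(tr) * (nocc - 1) / nocc -
                 config$hct$noise^2, 0)
  hct_base <- rnorm(n, mu_b, sqrt(var_b))

  eta <- cbind(rnorm(n, 0, sqrt(m$omega2[["v"]])),
               rnorm(n, 0, sqrt(m$omega2[["cl"]])))

  beta <- m$beta
  if (config$vori_cl_effect != 0)
    beta <- c(beta, COMED_VORI = config$vori_cl_effect)

  recs <- vector("list", n)
  truth <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                      cyp3a5 = geno, eta_v = eta[, 1], eta_cl = eta[, 2],
                      v_f = m$theta_v * exp(eta[, 1]), cl_f = NA_real_)
  tit <- config$titration
  for (i in seq_len(n)) {
    wt <- base_cov$WT[i]
    daily0 <- round(0.1 * wt / tit$round_mg) * tit$round_mg
    amt <- max(tit$round_mg, round(daily0 / 2 / tit$round_mg) * tit$round_mg)
    hct_i <- pmin(pmax(hct_base[i] + hct_trend(pods, config$hct) +
                         rnorm(nocc, 0, config$hct$noise), 0.12), 0.55)
    panel <- data.frame(WT = wt, HCT = hct_i,
                        RBC = pmax(base_cov$RBC[i] +
                                     rnorm(nocc, 0, 0.12), 1.0),
                        DBIL = pmax(base_cov$DBIL[i] *
                                      exp(rnorm(nocc, 0, 0.1)), 0.2),
                        BUN = pmax(base_cov$BUN[i] *
                                     exp(rnorm(nocc, 0, 0.1)), 1),
                        CLCR = pmax(base_cov$CLCR[i] *
                                      exp(rnorm(nocc, 0, 0.1)), 5),
                        ALB = pmax(base_cov$ALB[i] +
                                     rnorm(nocc, 0, 0.8), 15),
                        SEX = base_cov$SEX[i], CYP3A5 = geno[i],
                        COMED_CA = base_cov$COMED_CA[i],
                        COMED_PPI = base_cov$COMED_PPI[i],
                        COMED_VORI = base_cov$COMED_VORI[i])
    v_i <- m$theta_v * exp(eta[i, 1])
    # typical CL/F at each occasion's panel (time-varying via HCT)
    tvcl_occ <- m$theta_cl *
      exp(as.matrix(panel[, names(beta), drop = FALSE]) %*%
            unlist(beta))[, 1]
    cl_occ <- tvcl_occ * exp(eta[i, 2])
    truth$cl_f[i] <- cl_occ[1]

    dose_t <- numeric(0); dose_a <- numeric(0)
    conc <- numeric(nocc)
    prev_t <- 0
    for (j in seq_len(nocc)) {
      t_j <- pods[j] * 24
      new_t <- seq(prev_t, t_j, by = 12)
      dose_t <- c(dose_t, new_t)
      dose_a <- c(dose_a, rep(amt, length(new_t)))
      # piecewise-constant ke: dose events carry the previous panel (LOCF)
      occ_idx <- findInterval(dose_t, pods * 24)
      occ_idx[occ_idx == 0] <- 1
      ke_dose <- cl_occ[occ_idx] / v_i
      ev_time <- c(dose_t, t_j)
      ev_amt <- c(dose_a, 0)
      ev_obs <- c(rep(0L, length(dose_t)), 1L)
      ord <- order(ev_time, ev_amt > 0)
      ke_ev <- c(ke_dose, cl_occ[j] / v_i)[ord]
      res <- pk_propagate_cpp(ev_time[ord], ev_amt[ord], ev_obs[ord],
                              ke_ev, m$ka, FALSE)
      ctrue <- 1000 * res[1, 1] / v_i
      conc[j] <- ctrue * exp(rnorm(1, 0, sqrt(m$sigma2)))
      # titration against the POD-dependent target window
      w <- tit$windows[which(pods[j] <= tit$windows$pod_max)[1], ]
      if (conc[j] > w$hi) {
        amt <- max(tit$round_mg,
                   round(amt * tit$down / tit$round_mg) * tit$round_mg)
      } else if (conc[j] < w$lo) {
        amt <- round(amt * tit$up / tit$round_mg) * tit$round_mg
      }
      prev_t <- t_j + 12
    }
    cens <- ifelse(conc < config$assay_range[1], "low",
                   ifelse(conc > config$assay_range[2], "high", "none"))
    obs <- data.frame(time = pods * 24, conc = conc, pod = pods,
                      occasion = seq_len(nocc), censored = cens,
                      stringsAsFactors = FALSE)
    recs[[i]] <- tac_patient(truth$patient_id[i],
                             data.frame(time = dose_t, amt = dose_a),
                             obs, panel)
  }
  out <- as_cohort(recs)
  attr(out, "truth") <- truth
  out
}

#' Latent truth of a generated cohort
#'
#' Exposes the per-patient latent values used by [generate_cohort()]
#' (random effects and the implied individual V/F and CL/F at the first
#' occasion), enabling parameter- and EBE-recovery checks.
#'
#' @param cohort a cohort produced by [generate_cohort()].
#' @return data frame with one row per patient.
#' @export
truth_table <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr))
    stop("cohort was not produced by generate_cohort(); no latent truth")
  tr
}
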