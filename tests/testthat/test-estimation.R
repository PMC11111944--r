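test_that("the objective collapses to the fixed-effects likelihood as Omega -> 0", {
  m0 <- ppk_model(theta_v = 2000, theta_cl = 50, beta = numeric(0),
                  omega2_v = 0, omega2_cl = 0, sigma2 = 0.1)
  rec <- toy_simulate(toy_patient(), m0, sigma = 0.2, seed = 1)
  coh <- tacppk:::as_cohort(list(rec))
  got <- objective_function(coh, m0)
  ind <- individualize(m0, NULL, 0, 0)
  mu <- log(r_superpose(rec$obs$time, rec$doses, m0$ka, ind$ke, ind$v_f))
  want <- sum((log(rec$obs$conc) - mu)^2 / m0$sigma2 +
                log(2 * pi * m0$sigma2))
  expect_equal(as.numeric(got), want, tolerance = 1e-8)
})

test_that("FOCE agrees with adaptive Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  m <- ppk_model(theta_v = 2000, theta_cl = 45, beta = numeric(0),
                 omega2_v = 0.3, omega2_cl = 0.06, sigma2 = 0.12)
  r1 <- toy_simulate(toy_patient("S1", trough_pod = c(3, 7, 14)), m,
                     eta_v = 0.4, eta_cl = -0.2, sigma = 0.3, seed = 2)
  r2 <- toy_simulate(toy_patient("S2", amt = 6, trough_pod = c(3, 7, 14)),
                     m, eta_v = -0.5, eta_cl = 0.25, sigma = 0.3, seed = 3)
  coh <- tacppk:::as_cohort(list(r1, r2))
  foce <- as.numeric(objective_function(coh, m))
  agh <- agh_ofv(coh, m, n_nodes = 21)
  expect_lt(abs(foce - agh), 0.5)
})

test_that("the objective is additive over subjects and order-invariant", {
  m <- ppk_preset("basic")
  coh <- generate_cohort(small_config(6, pods = c(3, 7, 14, 30)), seed = 4)
  base <- objective_function(coh, m)
  dup <- tacppk:::as_cohort(c(unclass(coh), list({
    r <- coh[[3]]; r$patient_id <- "DUP"; r
  })))
  expect_equal(as.numeric(objective_function(dup, m)),
               as.numeric(base) + attr(base, "by_subject")[3],
               tolerance = 1e-8)
  perm <- tacppk:::as_cohort(unclass(coh)[c(4, 2, 6, 1, 5, 3)])
  expect_equal(as.numeric(objective_function(perm, m)),
               as.numeric(base), tolerance = 1e-9)
  relab <- tacppk:::as_cohort(lapply(unclass(coh), function(r) {
    r$patient_id <- paste0("X", r$patient_id); r
  }))
  expect_equal(as.numeric(objective_function(relab, m)),
               as.numeric(base), tolerance = 1e-12)
})

test_that("noise-free data identify the typical values to 4 significant digits", {
  m <- ppk_model(theta_v = 2200, theta_cl = 55, beta = numeric(0),
                 omega2_v = 0.2, omega2_cl = 0.05, sigma2 = 0.1)
  recs <- lapply(1:8, function(i)
    toy_simulate(toy_patient(paste0("N", i), amt = 2 + i %% 3,
                             days = 30, trough_pod = c(3, 7, 14, 21, 30)),
                 m, sigma = 0))
  coh <- tacppk:::as_cohort(recs)
  # eta == 0 in the generating process: pin the random effects and the
  # residual scale, estimate the typical values from displaced starts
  init <- ppk_model(theta_v = 3000, theta_cl = 40, beta = numeric(0),
                    omega2_v = 0, omega2_cl = 0, sigma2 = 1e-4)
  fit <- quiet_fit(coh, init = init, estimate_se = FALSE,
                   fix = c("omega2_v", "omega2_cl", "sigma2"))
  expect_equal(fit$estimates$theta_v, 2200, tolerance = 1e-4)
  expect_equal(fit$estimates$theta_cl, 55, tolerance = 1e-4)
})

test_that("refits from displaced starting values reach the same optimum", {
  coh <- generate_cohort(small_config(25, pods = c(3, 7, 14, 30, 60, 90)),
                         seed = 6)
  truth <- ppk_preset("basic")
  up <- ppk_model(theta_v = truth$theta_v * 1.5,
                  theta_cl = truth$theta_cl * 1.5, beta = numeric(0),
                  omega2_v = truth$omega2[["v"]] * 1.5,
                  omega2_cl = truth$omega2[["cl"]] * 1.5,
                  sigma2 = truth$sigma2 * 1.5)
  dn <- ppk_model(theta_v = truth$theta_v * 0.5,
                  theta_cl = truth$theta_cl * 0.5, beta = numeric(0),
                  omega2_v = truth$omega2[["v"]] * 0.5,
                  omega2_cl = truth$omega2[["cl"]] * 0.5,
                  sigma2 = truth$sigma2 * 0.5)
  f1 <- quiet_fit(coh, init = up, estimate_se = FALSE)
  f2 <- quiet_fit(coh, init = dn, estimate_se = FALSE)
  expect_lt(abs(f1$ofv - f2$ofv), 0.1)
})

test_that("MAP estimation matches a grid-search oracle", {
  m <- ppk_model(theta_v = 2000, theta_cl = 45, beta = numeric(0),
                 omega2_v = 0.3, omega2_cl = 0.06, sigma2 = 0.1)
  rec <- toy_simulate(toy_patient(trough_pod = c(3, 7, 10, 14)), m,
                      eta_v = 0.5, eta_cl = -0.3, sigma = 0.25, seed = 7)
  got <- map_individual(rec, m)
  grid <- seq(-2, 2, length.out = 101)
  obj <- function(e1, e2) {
    vf <- m$theta_v * exp(e1); ke <- m$theta_cl * exp(e2) / vf
    mu <- log(r_superpose(rec$obs$time, rec$doses, m$ka, ke, vf))
    sum((log(rec$obs$conc) - mu)^2) / m$sigma2 +
      e1^2 / m$omega2[["v"]] + e2^2 / m$omega2[["cl"]]
  }
  vals <- outer(grid, grid, Vectorize(obj))
  best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  res <- grid[2] - grid[1]
  expect_lt(abs(got$eta[["eta_v"]] - grid[best[1]]), res)
  expect_lt(abs(got$eta[["eta_cl"]] - grid[best[2]]), res)
})

test_that("MAP falls back to the prior mode without data and under huge noise", {
  m <- ppk_preset("basic")
  rec <- toy_patient()
  rec$obs <- rec$obs[0, ]
  rec$covariates <- rec$covariates[0, ]
  got <- map_individual(rec, m, at_times = numeric(0))
  expect_true(got$prior_only)
  expect_equal(unname(got$eta), c(0, 0))
  expect_length(got$ipre, 0)
  vague <- ppk_model(theta_v = m$theta_v, theta_cl = m$theta_cl,
                     beta = numeric(0), omega2_v = m$omega2[["v"]],
                     omega2_cl = m$omega2[["cl"]], sigma2 = 1e6)
  got2 <- map_individual(toy_patient(conc = c(20, 3, 11)), vague)
  expect_lt(max(abs(got2$eta)), 1e-3)
})

test_that("MAP modes shrink relative to the unpenalized individual fit", {
  m <- ppk_preset("basic")
  set.seed(8)
  for (i in 1:5) {
    rec <- toy_simulate(toy_patient(trough_pod = c(3, 7, 14, 21)), m,
                        eta_v = rnorm(1, 0, 0.5), eta_cl = rnorm(1, 0, 0.2),
                        sigma = 0.3, seed = 100 + i)
    map <- map_individual(rec, m)
    mfree <- ppk_model(theta_v = m$theta_v, theta_cl = m$theta_cl,
                       beta = numeric(0), omega2_v = 1e6, omega2_cl = 1e6,
                       sigma2 = m$sigma2)
    ml <- map_individual(rec, mfree)
    expect_lte(abs(map$eta[["eta_cl"]]), abs(ml$eta[["eta_cl"]]) + 1e-6)
  }
})

test_that("parameter recovery is unbiased with calibrated Wald intervals", {
  # simulate-and-refit at the study design; median bias and CI coverage
  reps <- lapply(1:20, function(s) {
    coh <- generate_cohort(cohort_config(n_patients = 103), seed = 300 + s)
    f <- quiet_fit(coh, init = ppk_preset("final"),
                   control = list(rel_tol = 1e-6))
    v <- f$vcov["theta_cl", "theta_cl"]
    se_cl <- if (is.finite(v) && v > 0) sqrt(v) else NA_real_
    list(thcl = f$estimates$theta_cl,
         thv = f$estimates$theta_v,
         cover = abs(f$estimates$theta_cl - 70.6) < qnorm(0.975) * se_cl)
  })
  thcl <- vapply(reps, `[[`, 0, "thcl")
  thv <- vapply(reps, `[[`, 0, "thv")
  expect_lt(abs(median(thcl) - 70.6) / 70.6, 0.10)
  expect_lt(abs(median(thv) - 2560) / 2560, 0.10)
  cover <- vapply(reps, `[[`, TRUE, "cover")
  expect_gte(sum(!is.na(cover)), 15)  # the curvature is usable almost always
  expect_gte(mean(cover, na.rm = TRUE), 0.75)
})
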