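test_that("error metrics implement the printed formulas", {
  r <- prediction_error_report(c(10, 5), c(12, 4))
  expect_equal(r$mae, 1.5)
  expect_equal(r$mape_pct, 20)
  expect_equal(r$rmse, sqrt(2.5))
  expect_equal(r$mpe_pct, 0)  # (+20% - 20%) / 2
  p <- prediction_error_report(c(3, 7, 9), c(3, 7, 9))
  expect_equal(p$mae, 0); expect_equal(p$mape_pct, 0)
  expect_equal(p$rmse, 0); expect_equal(p$mpe_pct, 0)
  expect_equal(p$r2, 1)
  obs <- c(4, 8, 12)
  expect_equal(prediction_error_report(obs, rep(mean(obs), 3))$r2, 0)
  expect_error(prediction_error_report(c(0, 1), c(1, 1)), "0")
})

test_that("RMSE dominates MAE and R2 never exceeds 1", {
  set.seed(9)
  for (i in 1:20) {
    obs <- runif(30, 2, 20)
    pred <- obs * exp(rnorm(30, 0, 0.3))
    r <- prediction_error_report(obs, pred)
    expect_gte(r$rmse, r$mae)
    expect_lte(r$r2, 1)
    expect_gte(r$mrse_pct, 0)
  }
})

test_that("swapping observed and predicted flips the error asymmetrically", {
  a <- prediction_error_report(c(10, 5), c(12, 4))
  b <- prediction_error_report(c(12, 4), c(10, 5))
  expect_equal(a$mae, b$mae)          # absolute error is symmetric
  expect_false(isTRUE(all.equal(a$mpe_pct, -b$mpe_pct)))  # relative is not
})

test_that("a one-observation subject matches the scalar CWRES formula", {
  m <- ppk_model(theta_v = 2000, theta_cl = 45, beta = numeric(0),
                 omega2_v = 0.3, omega2_cl = 0.06, sigma2 = 0.1)
  rec <- toy_simulate(toy_patient(trough_pod = 7), m,
                      eta_v = 0.3, eta_cl = -0.2, sigma = 0.3, seed = 31)
  got <- cwres(tacppk:::as_cohort(list(rec)), m)
  # scalar oracle: eta-hat by direct optimization, G by finite differences
  lpred <- function(e1, e2) {
    vf <- m$theta_v * exp(e1); ke <- m$theta_cl * exp(e2) / vf
    log(r_superpose(rec$obs$time, rec$doses, m$ka, ke, vf))
  }
  obj <- function(p) (log(rec$obs$conc) - lpred(p[1], p[2]))^2 / m$sigma2 +
    p[1]^2 / m$omega2[["v"]] + p[2]^2 / m$omega2[["cl"]]
  eta <- optim(c(0, 0), obj)$par
  h <- 1e-5
  G <- c((lpred(eta[1] + h, eta[2]) - lpred(eta[1] - h, eta[2])) / (2 * h),
         (lpred(eta[1], eta[2] + h) - lpred(eta[1], eta[2] - h)) / (2 * h))
  V <- G[1]^2 * m$omega2[["v"]] + G[2]^2 * m$omega2[["cl"]] + m$sigma2
  want <- (log(rec$obs$conc) - lpred(eta[1], eta[2]) + sum(G * eta)) /
    sqrt(V)
  expect_equal(unname(got), want, tolerance = 1e-3)
})

test_that("CWRES are calibrated under the generating model", {
  coh <- generate_cohort(small_config(50), seed = 33)
  cw <- cwres(coh, ppk_preset("final"))
  expect_gte(length(cw), 350)
  expect_lt(abs(mean(cw)), 0.1)
  expect_gt(var(cw), 0.8); expect_lt(var(cw), 1.2)
})

test_that("residual-dominated CWRES approach the population residual", {
  m <- ppk_model(theta_v = 2000, theta_cl = 45, beta = numeric(0),
                 omega2_v = 0.01, omega2_cl = 0.01, sigma2 = 25)
  rec <- toy_simulate(toy_patient(trough_pod = c(3, 7, 14)), m,
                      sigma = 0.3, seed = 35)
  got <- cwres(tacppk:::as_cohort(list(rec)), m)
  ind <- individualize(m, NULL, 0, 0)
  naive <- (log(rec$obs$conc) -
              log(r_superpose(rec$obs$time, rec$doses, m$ka, ind$ke,
                              ind$v_f))) / sqrt(m$sigma2)
  expect_equal(unname(got), naive, tolerance = 0.05)
})

test_that("the VPC is deterministic in the seed and degenerates without noise", {
  coh <- generate_cohort(small_config(15, pods = c(3, 7, 14, 30, 60)),
                         seed = 37)
  v1 <- suppressWarnings(vpc(coh, ppk_preset("final"), n_replicates = 60,
                             seed = 5, bins = 4))
  v2 <- suppressWarnings(vpc(coh, ppk_preset("final"), n_replicates = 60,
                             seed = 5, bins = 4))
  expect_identical(v1$sim_pct_ci, v2$sim_pct_ci)
  expect_warning(vpc(coh, ppk_preset("final"), n_replicates = 50, seed = 1,
                     bins = 4), "replicates")
  m0 <- ppk_model(omega2_v = 0, omega2_cl = 0, sigma2 = 1e-12)
  v0 <- suppressWarnings(vpc(coh, m0, n_replicates = 100, seed = 2,
                             bins = 4))
  width <- v0$sim_pct_ci[3, , ] - v0$sim_pct_ci[1, , ]
  expect_lt(max(width), 1e-3)  # collapses to the deterministic prediction
})

test_that("VPC percentile bands widen with the residual variance", {
  coh <- generate_cohort(small_config(15, pods = c(3, 7, 14, 30, 60)),
                         seed = 38)
  w <- vapply(c(0.05, 0.2, 0.5), function(s2) {
    m <- ppk_model(omega2_v = 0.2, omega2_cl = 0.05, sigma2 = s2)
    v <- suppressWarnings(vpc(coh, m, n_replicates = 150, seed = 4,
                              bins = 3))
    # pooled 5th-95th band width, averaged over bins
    mean(v$sim_pct_ci[2, , 3] - v$sim_pct_ci[2, , 1])
  }, 0)
  expect_true(all(diff(w) > 0))
})
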