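test_that("typical clearance evaluates the covariate submodel", {
  m <- ppk_model(theta_cl = 70.6, beta = c(CYP3A5 = -0.348, HCT = -0.122))
  expect_equal(typical_clearance(m, 0, 0), 70.6)
  expect_equal(typical_clearance(m, 1, 0.29),
               70.6 * exp(-0.348) * exp(-0.122 * 0.29), tolerance = 1e-12)
  expect_equal(round(typical_clearance(m, 1, 0.29), 1), 48.1)
  expect_error(typical_clearance(m, 3, 0.3), "cyp3a5_code")
})

test_that("genotype clearance ratios depend only on the coefficients", {
  for (th in c(10, 70.6, 300)) {
    m <- ppk_model(theta_cl = th, beta = c(CYP3A5 = -0.348, HCT = -0.122))
    r1 <- typical_clearance(m, 1, 0.3) / typical_clearance(m, 0, 0.3)
    r2 <- typical_clearance(m, 2, 0.3) / typical_clearance(m, 0, 0.3)
    expect_equal(r1, exp(-0.348), tolerance = 1e-12)
    expect_equal(r2, exp(-0.696), tolerance = 1e-12)
  }
})

test_that("individual parameters follow the exponential random-effect model", {
  m <- ppk_preset("basic")
  i0 <- individualize(m, NULL, 0, 0)
  expect_equal(i0$v_f, m$theta_v)
  expect_equal(i0$cl_f, m$theta_cl)
  expect_equal(individualize(m, NULL, 0, log(2))$cl_f, 2 * m$theta_cl)
  m2 <- ppk_model(theta_v = 2560, beta = numeric(0))
  expect_equal(individualize(m2, NULL, 0.1, 0)$v_f, 2560 * exp(0.1))
  expect_equal(round(individualize(m2, NULL, 0.1, 0)$v_f, 1), 2829.2)
})

test_that("predicted concentrations wash out after the last dose", {
  ind <- individualize(ppk_preset("basic"), NULL, 0, 0)
  d <- data.frame(time = c(0, 12, 24), amt = 5)
  expect_lt(predict_concentration(ind, 3.86, d, 24 + 1e6), 1e-6)
})

test_that("the closed-form prediction matches an ODE integrator", {
  skip_if_not_installed("deSolve")
  ind <- individualize(ppk_model(theta_v = 2560, theta_cl = 70.6,
                                 beta = numeric(0)), NULL, 0, 0)
  d <- data.frame(time = 0, amt = 5)
  got <- predict_concentration(ind, 3.86, d, 12)
  want <- ode_conc(12, d, 3.86, ind$ke, ind$v_f)
  expect_lt(abs(got - want) / want, 1e-3)
  # property: random parameter draws, multi-dose schedules
  set.seed(42)
  for (rep in 1:5) {
    vf <- runif(1, 500, 5000); cl <- runif(1, 10, 150)
    ka <- runif(1, 1, 6)
    d <- data.frame(time = seq(0, 60, by = 12),
                    amt = round(runif(6, 1, 8) * 2) / 2)
    ind <- list(v_f = vf, ke = cl / vf)
    t_q <- c(13, 36.5, 71.9)
    got <- predict_concentration(ind, ka, d, t_q)
    want <- ode_conc(t_q, d, ka, cl / vf, vf)
    expect_lt(max(abs(got - want) / want), 1e-3)
  }
})

test_that("a long BID regimen reaches the steady-state closed form", {
  vf <- 2000; cl <- 40; ka <- 3.86; ke <- cl / vf; tau <- 12
  d <- data.frame(time = seq(0, by = tau, length.out = 30), amt = 4)
  got <- predict_concentration(list(v_f = vf, ke = ke), ka, d, 30 * tau)
  want <- ss_trough(4, tau, ka, ke, vf)
  expect_lt(abs(got - want) / want, 0.005)
})

test_that("superposition is linear in dose and shift-invariant in time", {
  ind <- list(v_f = 1800, ke = 0.02)
  d <- data.frame(time = c(0, 12, 24, 48), amt = c(3, 3, 4, 5))
  t_q <- c(30, 60, 90)
  base <- predict_concentration(ind, 3.86, d, t_q)
  d2 <- transform(d, amt = 2 * amt)
  expect_equal(predict_concentration(ind, 3.86, d2, t_q), 2 * base,
               tolerance = 1e-12)
  shift <- 1000
  d3 <- transform(d, time = time + shift)
  expect_equal(predict_concentration(ind, 3.86, d3, t_q + shift), base,
               tolerance = 1e-9)
})

test_that("the absorption-elimination degeneracy uses the limiting form", {
  vf <- 100
  d <- data.frame(time = 0, amt = 5)
  ka <- 0.5
  near <- predict_concentration(list(v_f = vf, ke = ka * (1 + 1e-10)),
                                ka, d, 6)
  lim <- 1000 * 5 / vf * ka * 6 * exp(-ka * 6)  # ke -> ka limit
  expect_equal(near, lim, tolerance = 1e-6)
  expect_true(is.finite(near))
})
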