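test_that("a noise-free homogeneous cohort is fully degenerate", {
  cc <- small_config(6, pods = c(3, 7, 14, 30))
  cc$model <- ppk_model(omega2_v = 0, omega2_cl = 0, sigma2 = 0)
  cc$covariates$WT <- list(dist = "tnorm", mean = 60, sd = 0)
  cc$genotype_freqs <- c(0, 0, 1)
  cc$hct <- list(mean = 0.3, sd = 0, amp = 0, tau = 90, noise = 0)
  coh <- generate_cohort(cc, seed = 41)
  concs <- vapply(coh, function(r) r$obs$conc, numeric(4))
  expect_lt(max(apply(concs, 1, sd)), 1e-9)
  doses <- vapply(coh, function(r) r$doses$amt[nrow(r$doses)], 0)
  expect_equal(length(unique(doses)), 1L)
  tr <- truth_table(coh)
  expect_true(all(tr$eta_v == 0) && all(tr$eta_cl == 0))
})

test_that("genotype sampling matches the configured frequencies", {
  coh <- generate_cohort(small_config(127, pods = c(3, 7)), seed = 43)
  g <- truth_table(coh)$cyp3a5
  counts <- table(factor(g, levels = 0:2))
  p <- c(0.0945, 0.339, 0.567) / sum(c(0.0945, 0.339, 0.567))
  for (k in 1:3) {
    ci <- qbinom(c(0.025, 0.975), 127, p[k])
    expect_gte(counts[k], ci[1]); expect_lte(counts[k], ci[2])
  }
})

test_that("generated cohorts satisfy the data-model invariants", {
  for (s in c(1, 99)) {
    coh <- generate_cohort(small_config(8), seed = s)
    for (r in coh) expect_silent(tacppk:::validate_patient(r))
    expect_identical(generate_cohort(small_config(8), seed = s)[[3]]$obs,
                     coh[[3]]$obs)  # reproducible by seed
  }
  expect_error(cohort_config(covariates = list(
    WT = list(dist = "tnorm", mean = 60, sd = -1))), "negative")
})

test_that("covariate marginals match their configuration", {
  coh <- generate_cohort(small_config(500, pods = c(3, 30, 90, 210, 365)),
                         seed = 47)
  wt <- vapply(coh, function(r) r$covariates$WT[1], 0)
  expect_lt(abs(mean(wt) - 63.3), 3 * 12.9 / sqrt(500))
  expect_lt(abs(sd(wt) - 12.9), 3 * 12.9 / sqrt(250))
  alb <- vapply(coh, function(r) r$covariates$ALB[1], 0)
  expect_lt(abs(mean(alb) - 34.0), 3 * 3.69 / sqrt(500))
  hct <- unlist(lapply(coh, function(r) r$covariates$HCT))
  expect_lt(abs(mean(hct) - 0.29), 0.01)
  expect_lt(abs(sd(hct) - 0.056), 0.01)
})

test_that("titration concentrates troughs into the target window", {
  coh <- generate_cohort(cohort_config(n_patients = 120), seed = 49)
  inwin <- function(r, occ) {
    o <- r$obs[r$obs$occasion %in% occ, ]
    w_lo <- ifelse(o$pod <= 30, 10, 5); w_hi <- ifelse(o$pod <= 30, 13, 9)
    c(sum(o$conc >= w_lo & o$conc <= w_hi), nrow(o))
  }
  early <- rowSums(vapply(coh, inwin, numeric(2), occ = 1:2))
  late <- rowSums(vapply(coh, inwin, numeric(2), occ = 5:8))
  expect_gt(late[1] / late[2], early[1] / early[2])
})

test_that("the truth table records the cohort's latent values", {
  coh <- generate_cohort(small_config(12, pods = c(3, 7, 14)), seed = 51)
  tr <- truth_table(coh)
  expect_equal(nrow(tr), 12)
  expect_equal(tr$patient_id, vapply(coh, `[[`, "", "patient_id"))
  expect_equal(tr$v_f, 2560 * exp(tr$eta_v))
  plain <- coh[seq_along(coh)]  # subsetting drops the latent attribute
  expect_error(truth_table(plain), "latent truth")
})

test_that("MAP modes track the latent random effects", {
  coh <- generate_cohort(cohort_config(n_patients = 103), seed = 53)
  fit <- quiet_fit(coh, init = ppk_preset("final"), estimate_se = FALSE)
  tr <- truth_table(coh)
  expect_gt(cor(fit$ebes$eta_cl, tr$eta_cl), 0.7)
})
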