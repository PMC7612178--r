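test_that("without confounding the oracle matches the closed form exactly", {
  hz <- additive_hazard_spec(alpha0 = 0.7, alphaA = -0.2, alphaL = 0,
                             alphaU = 0)
  cov <- covariate_process_spec()
  for (rg in list(never_treated(4), always_treated(4))) {
    s <- marginal_survival_mc(rg, hz, cov, N = 100, seed = 1, times = 1:5)
    a <- as.integer(rg)
    closed <- exp(-cumsum(0.7 - 0.2 * a))
    expect_equal(s$survival, closed, tolerance = 1e-12)
    expect_equal(s$survival_se, rep(0, 5), tolerance = 1e-12)
    h <- marginal_hazard_mc(rg, hz, cov, N = 100, seed = 1, t = 0.5)
    expect_equal(h$hazard, 0.7 - 0.2 * a[1], tolerance = 1e-12)
  }
})

test_that("the marginal hazard contrast on (0,1) equals the lag-0 coefficient", {
  hz <- additive_hazard_spec()
  cov <- covariate_process_spec()
  # common random numbers: the confounder terms cancel exactly in the
  # contrast, leaving the conditional treatment coefficient
  for (t in c(0.25, 0.5, 0.9)) {
    h1 <- marginal_hazard_mc(treatment_regime(c(1, 0, 0, 0, 0)), hz, cov,
                             N = 5000, seed = 5, t = t)
    h0 <- marginal_hazard_mc(never_treated(4), hz, cov,
                             N = 5000, seed = 5, t = t)
    expect_equal(h1$hazard - h0$hazard, -0.2, tolerance = 1e-10)
  }
})

test_that("oracle survival agrees with intervention-trial proportions", {
  hz <- additive_hazard_spec()
  cov <- covariate_process_spec()
  m <- 3e4
  trial <- simulate_under_regimes(list(never_treated(4), always_treated(4)),
                                  m = m, seed = 7, hazard = hz,
                                  covariates = cov)
  for (rg in list(never_treated(4), always_treated(4))) {
    lab <- attr(rg, "label")
    sub <- trial[trial$regime == lab & trial$visit == 0, ]
    s_mc <- marginal_survival_mc(rg, hz, cov, N = 5e4, seed = 8, times = 1:5)
    for (i in 1:5) {
      prop <- mean(!(sub$event == 1 & sub$T <= i))
      se_prop <- sqrt(prop * (1 - prop) / m)
      se_comb <- sqrt(se_prop^2 + s_mc$survival_se[i]^2)
      expect_lt(abs(prop - s_mc$survival[i]), 3.5 * se_comb)
    }
  }
})

test_that("the marginal hazard is minus the derivative of log survival", {
  hz <- additive_hazard_spec()
  cov <- covariate_process_spec()
  rg <- always_treated(4)
  h <- marginal_hazard_mc(rg, hz, cov, N = 1e5, seed = 9, t = 1.5)
  s <- marginal_survival_mc(rg, hz, cov, N = 1e5, seed = 9,
                            times = c(1.49, 1.51))
  numeric_h <- -(log(s$survival[2]) - log(s$survival[1])) / 0.02
  expect_lt(abs(numeric_h - h$hazard), 3 * h$se + 1e-4)
})

test_that("the implied MSM reproduces theory on (0,1) and at null mediation", {
  hz <- additive_hazard_spec()
  cov <- covariate_process_spec()
  imp <- implied_additive_msm(hz, cov, N = 4e4, seed = 11, times = 1:5)
  # lag-0 cumulative coefficient on (0,1) equals the conditional one
  expect_lt(abs(imp$cum["1", "lag0"] - (-0.2)), 0.01)
  # baseline equals -log never-treated survival on the same ensemble
  s_nev <- marginal_survival_mc(never_treated(4), hz, cov, N = 4e4,
                                seed = 11, times = 1:5)
  expect_equal(unname(imp$cum[, "baseline"]), -log(s_nev$survival),
               tolerance = 1e-10)
  # lag-j structural zeros for t <= j
  expect_equal(imp$cum["1", paste0("lag", 1:4)],
               c(lag1 = 0, lag2 = 0, lag3 = 0, lag4 = 0))

  # treatment not affecting L (and no frailty in the hazard): no lagged
  # effects survive marginalization
  hz0 <- additive_hazard_spec(alphaU = 0)
  cov0 <- covariate_process_spec(theta_a = 0)
  imp0 <- implied_additive_msm(hz0, cov0, N = 4e4, seed = 13, times = 1:5)
  expect_lt(max(abs(imp0$cum[, paste0("lag", 1:4)])), 0.01)
  # additivity diagnostic indistinguishable from zero here
  expect_lt(abs(imp0$additivity$stat), 4 * imp0$additivity$se + 1e-6)
})

test_that("additivity of the implied MSM holds at the default generator", {
  imp <- implied_additive_msm(additive_hazard_spec(),
                              covariate_process_spec(),
                              N = 1e5, seed = 15, times = 1:5)
  # maximum two-way interaction contrast of -log S across regime pairs.
  # With a linear confounder process and no hazard flooring the
  # treatment-dependent part of each path's cumulative hazard is
  # deterministic, so the contrast vanishes to machine precision and its
  # influence-function SE degenerates with it; the epsilon covers that.
  expect_lt(abs(imp$additivity$stat), 4 * imp$additivity$se + 1e-10)
})

test_that("marginal curves behave as survival functions", {
  s <- marginal_survival_mc(always_treated(4), additive_hazard_spec(),
                            covariate_process_spec(), N = 2e4, seed = 17,
                            times = c(0, 0.5, 1:5))
  expect_equal(s$survival[1], 1)
  expect_true(all(diff(s$survival) <= 1e-12))
  expect_true(all(s$survival_se >= 0))
  expect_error(marginal_survival_mc(always_treated(4),
                                    additive_hazard_spec(),
                                    covariate_process_spec(), N = 1,
                                    seed = 1, times = 1), "N")
})

test_that("Cox-family marginal hazard ratios attenuate with frailty", {
  cov <- covariate_process_spec()
  # no confounder/frailty effects: the log marginal HR for the visit-0
  # contrast is constant at betaA over (0, 1), the period where a_0 drives
  # the conditional hazard
  hz_null <- cox_hazard_spec(lambda0 = 0.5, betaA = -0.4, betaL = 0,
                             betaU = 0)
  curve0 <- cox_marginal_hazard_mc(never_treated(4), hz_null, cov, N = 5e3,
                                   seed = 19, times = c(0.1, 0.5, 0.9))
  expect_equal(curve0$log_hr, rep(-0.4, 3), tolerance = 1e-10)

  # strong frailty: the log HR starts at betaA (up to O(t) selection at a
  # small positive t) and attenuates as high-frailty subjects die
  hz_fr <- cox_hazard_spec(lambda0 = 0.5, betaA = -0.4, betaL = 0, betaU = 1)
  cov_fr <- covariate_process_spec(u_sd = 1)
  curve <- cox_marginal_hazard_mc(never_treated(4), hz_fr, cov_fr, N = 1e5,
                                  seed = 21, times = c(0.01, 0.5, 0.75, 0.95))
  expect_lt(abs(curve$log_hr[1] - (-0.4)), 3 * curve$log_hr_se[1] + 0.015)
  drift <- abs(curve$log_hr[4] - curve$log_hr[1])
  expect_gt(drift, 3 * sqrt(curve$log_hr_se[1]^2 + curve$log_hr_se[4]^2))

  # quadrupling the path count halves the Monte-Carlo SE
  c1 <- cox_marginal_hazard_mc(never_treated(4), hz_fr, cov_fr, N = 4e3,
                               seed = 23, times = 1)
  c4 <- cox_marginal_hazard_mc(never_treated(4), hz_fr, cov_fr, N = 16e3,
                               seed = 23, times = 1)
  expect_gt(c1$log_hr_se / c4$log_hr_se, 1.5)
  expect_lt(c1$log_hr_se / c4$log_hr_se, 2.7)
})
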