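test_that("constant-hazard event draws match the closed form", {
  expect_equal(draw_event_time_constant(0.7, 1, 0.5), -log(0.5) / 0.7)
  expect_equal(draw_event_time_constant(0.7, 1, exp(-0.35)), 0.5)
  # negative hazard is floored at 0: no event possible
  expect_true(is.na(draw_event_time_constant(-0.05, 1, 0.5)))
  expect_true(is.na(draw_event_time_constant(-0.05, 1, 1e-9)))
  # a draw landing exactly on the boundary survives (strict inequality)
  expect_true(is.na(draw_event_time_constant(0.7, 0.5, exp(-0.35))))
  expect_error(draw_event_time_constant(0.7, 1, 0), "uniform")
  expect_error(draw_event_time_constant(0.7, 1, 1), "uniform")
})

test_that("piecewise-exponential draws invert the cumulative hazard", {
  # single step reduces exactly to the constant-hazard draw
  for (v in c(0.13, 0.5, 0.92)) {
    expect_equal(draw_event_time_piecewise(0.7, c(0, 1), v),
                 draw_event_time_constant(0.7, 1, v))
  }
  # two steps: Lambda(0.5) = 0.25, remaining 0.25 at rate 1 -> t = 0.75
  expect_equal(draw_event_time_piecewise(c(0.5, 1), c(0, 0.5, 1), exp(-0.5)),
               0.75)
  # negative steps floored
  expect_true(is.na(draw_event_time_piecewise(c(-1, -2), c(0, 0.5, 1), 0.5)))

  # empirical survivor function of many draws matches exp(-Lambda(t))
  set.seed(99)
  V <- runif(2e4)
  draws <- vapply(V, function(v)
    draw_event_time_piecewise(c(0.4, 1.2, 0.8), c(0, 0.5, 1, 2), v),
    numeric(1))
  Lam <- function(t) 0.4 * pmin(t, 0.5) + 1.2 * pmax(pmin(t, 1) - 0.5, 0) +
    0.8 * pmax(pmin(t, 2) - 1, 0)
  for (t in c(0.3, 0.75, 1.5)) {
    s_hat <- mean(is.na(draws) | draws > t)
    s_true <- exp(-Lam(t))
    expect_lt(abs(s_hat - s_true),
              3 * sqrt(s_true * (1 - s_true) / length(V)))
  }
})

test_that("baseline treatment prevalence matches the logistic-normal integral", {
  # A_0 | L_0 ~ Bernoulli(expit(-2 + 0.5 L_0)), L_0 ~ N(0, 1 + 0.1^2)
  oracle <- stats::integrate(function(l)
    stats::plogis(-2 + 0.5 * l) * stats::dnorm(l, 0, sqrt(1.01)),
    -Inf, Inf)$value
  panel <- simulate_observational(1e5, seed = 21)
  p_hat <- mean(panel$A[panel$visit == 0])
  expect_lt(abs(p_hat - oracle), 3 * sqrt(oracle * (1 - oracle) / 1e5))
})

test_that("simulation is reproducible and substreams are coupled", {
  a <- simulate_observational(200, seed = 17)
  b <- simulate_observational(200, seed = 17)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # with every U pathway switched off, the output is invariant to the
  # frailty scale (shared covariate/treatment/event streams)
  haz <- additive_hazard_spec(alphaU = 0)
  c1 <- simulate_observational(200, hazard = haz, seed = 17,
    covariates = covariate_process_spec(u_sd = 0.1, l0_u_coef = 0, theta_u = 0))
  c2 <- simulate_observational(200, hazard = haz, seed = 17,
    covariates = covariate_process_spec(u_sd = 5, l0_u_coef = 0, theta_u = 0))
  expect_identical(c1$L, c2$L)
  expect_identical(c1$A, c2$A)
  expect_identical(c1$T, c2$T)
})

test_that("within-interval survival given covariates is exp(-lambda)", {
  panel <- simulate_observational(1e5, seed = 31)
  base <- panel[panel$visit == 0, ]
  lam <- default_hazard_value(base$A, base$L, base$U)
  p_event <- 1 - exp(-pmax(lam, 0))
  died <- as.numeric(base$event == 1 & base$T <= 1)
  # mean residual of the per-person Bernoulli event indicator
  se <- sqrt(sum(p_event * (1 - p_event))) / nrow(base)
  expect_lt(abs(mean(died) - mean(p_event)), 3 * se)
})

test_that("regime trials set treatment by intervention and share baselines", {
  regs <- all_regimes(K = 4)
  expect_length(regs, 32L)
  expect_equal(unique(vapply(regs, length, integer(1))), 5L)

  trial <- simulate_under_regimes(list(never_treated(2), always_treated(2)),
                                  m = 300, K = 2, seed = 9)
  nev <- trial[trial$regime == "000", ]
  alw <- trial[trial$regime == "111", ]
  expect_true(all(nev$A == 0L))
  expect_true(all(alw$A == 1L))
  # the realized L_0 values are identical across regime arms
  expect_identical(nev$L[nev$visit == 0], alw$L[alw$visit == 0])
  expect_identical(nev$U[nev$visit == 0], alw$U[alw$visit == 0])

  expect_warning(
    simulate_under_regimes(list(never_treated(2), never_treated(2)),
                           m = 20, K = 2, seed = 9),
    "duplicate")
})

test_that("conditional-Cox generator matches its within-interval law", {
  # no confounder/frailty effect: survival on (0,1) is exp(-lambda0 e^{bA a})
  hz <- cox_hazard_spec(lambda0 = 0.5, betaA = -0.3, betaL = 0, betaU = 0)
  panel <- simulate_conditional_cox(4e4, hazard = hz, seed = 41)
  base <- panel[panel$visit == 0, ]
  for (a in 0:1) {
    sub <- base[base$A == a, ]
    s_true <- exp(-0.5 * exp(-0.3 * a))
    s_hat <- mean(!(sub$event == 1 & sub$T <= 1))
    expect_lt(abs(s_hat - s_true),
              3 * sqrt(s_true * (1 - s_true) / nrow(sub)))
  }

  # with covariate effects: per-person event probability in (0,1) given
  # (A_0, L_0, U) is 1 - exp(-lambda0 e^{lp}), checked as a mean residual
  hz2 <- cox_hazard_spec(lambda0 = 0.5, betaA = -0.3, betaL = 0.2, betaU = 1)
  p2 <- simulate_conditional_cox(4e4, hazard = hz2, seed = 43)
  b2 <- p2[p2$visit == 0, ]
  lam <- 0.5 * exp(-0.3 * b2$A + 0.2 * b2$L + 1 * b2$U)
  p_event <- 1 - exp(-lam)
  died <- as.numeric(b2$event == 1 & b2$T <= 1)
  se <- sqrt(sum(p_event * (1 - p_event))) / nrow(b2)
  expect_lt(abs(mean(died) - mean(p_event)), 3 * se)
})

test_that("random censoring behaves as specified", {
  panel <- simulate_observational(500, seed = 51)
  expect_identical(apply_random_censoring(panel, list(c0 = 0), seed = 1),
                   panel)
  cens <- apply_random_censoring(panel, list(c0 = 0.3), seed = 1)
  per <- cens[!duplicated(cens$id), ]
  expect_true(all(per$C > 0))
  expect_true(all(per$C <= 5))
  expect_true(any(per$C < 5))             # some non-administrative censoring
  expect_true(all(per$event[!is.na(per$T)] == 1L))
  validate_panel(cens)

  # drawn censoring times are exponential(c): compare the empirical survivor
  # function of C among persons censored before any event competition by
  # using a generator with a tiny event hazard
  quiet <- simulate_observational(4e4, seed = 53,
    hazard = additive_hazard_spec(alpha0 = 1e-4, alphaA = 0, alphaL = 0,
                                  alphaU = 0))
  qc <- apply_random_censoring(quiet, list(c0 = 0.4), seed = 2)
  Cs <- qc$C[!duplicated(qc$id)]
  for (t in c(0.5, 1.5, 3)) {
    s_true <- exp(-0.4 * t)
    s_hat <- mean(Cs > t)
    expect_lt(abs(s_hat - s_true), 3 * sqrt(s_true * (1 - s_true) / length(Cs)))
  }
})
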