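test_that("disposition constants satisfy the sum and product identities", {
  p <- theta_ref()
  d <- disposition_constants(p)
  expect_equal(d$alpha + d$beta, d$k10 + d$k12 + d$k21, tolerance = 1e-12)
  expect_equal(d$alpha * d$beta, d$k10 * d$k21, tolerance = 1e-12)
  expect_gt(d$alpha, d$beta)
  expect_false(d$degenerate)

  # one-compartment limit: q = 0 collapses to alpha = k10, beta = 0
  d0 <- disposition_constants(pk_params(2, 0, 30, 50))
  expect_true(d0$degenerate)
  expect_equal(d0$alpha, 2 / 30)
  expect_equal(d0$beta, 0)

  # symmetric case vc = vp, cl = q gives k12 = k21 = k10
  ds <- disposition_constants(pk_params(3, 3, 40, 40))
  expect_equal(ds$k12, ds$k10)
  expect_equal(ds$k21, ds$k10)

  expect_error(pk_params(-1, 4, 30, 50), "positive")
})

test_that("analytic concentration matches ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  for (i in 1:20) {
    p <- pk_params(cl = runif(1, 0.5, 6), q = runif(1, 1, 12),
                   vc = runif(1, 15, 60), vp = runif(1, 25, 120))
    reg <- regimen(dose = runif(1, 250, 1500), interval = sample(c(12, 24), 1),
                   infusion_duration = runif(1, 0.5, 2), n_doses = 8)
    sched <- vancopk:::dose_schedule(reg)
    tt <- sort(runif(6, 0.1, reg$interval * reg$n_doses))
    a <- concentration(p, reg, tt)
    o <- ode_conc(p, sched, tt)
    expect_lt(max(abs(a - o) / pmax(o, 1e-12)), 1e-6)
  }
})

test_that("concentration handles boundary cases and scales linearly", {
  p <- theta_ref()
  reg <- regimen(750, 12, 1, n_doses = 10)
  # nothing on board before (or at) the first dose
  expect_identical(concentration(p, reg, 0), 0)
  expect_error(concentration(p, reg, -1), ">= 0")

  # bolus limit: infusion duration -> 0 gives dose/Vc just after dosing
  bol <- regimen(500, 12, 0, n_doses = 1)
  expect_equal(concentration(p, bol, 1e-7), 500 / 31.78, tolerance = 1e-4)

  # linear pharmacokinetics: doubling every dose doubles the profile
  tt <- c(2, 13, 95, 110)
  reg2 <- regimen(1500, 12, 1, n_doses = 10)
  expect_equal(concentration(p, reg2, tt), 2 * concentration(p, reg, tt),
               tolerance = 1e-12)
})

test_that("steady-state closed form agrees with long superposition", {
  p <- theta_ref()
  reg <- regimen(750, 12, 1, n_doses = 10)
  ss <- steady_state_peak_trough(p, reg)
  long <- concentration(p, regimen(750, 12, 1, n_doses = 500),
                        499 * 12 + c(1, 12))
  expect_equal(ss$peak, long[1], tolerance = 1e-4)
  expect_equal(ss$trough, long[2], tolerance = 1e-4)
  expect_lte(ss$trough, ss$peak)

  # washout: interval -> infinity sends the trough to zero
  wide <- steady_state_peak_trough(p, regimen(750, 2000, 1))
  expect_lt(wide$trough, 1e-6)

  # linearity of the steady-state solution
  ss2 <- steady_state_peak_trough(p, regimen(1500, 12, 1))
  expect_equal(ss2$peak, 2 * ss$peak, tolerance = 1e-12)
  expect_equal(ss2$trough, 2 * ss$trough, tolerance = 1e-12)
})

test_that("steady-state AUC identity holds against quadrature", {
  p <- theta_ref()
  reg <- regimen(750, 12, 1, n_doses = 10)
  auc_tau <- integrate(function(t) steady_state_concentration(p, reg, t),
                       0, 12, rel.tol = 1e-10)$value
  expect_equal(auc_tau, 750 / 1.96, tolerance = 1e-6)

  expect_equal(steady_state_auc24(1.96, 1500), 765.3, tolerance = 1e-4)
  expect_equal(steady_state_auc24(2.0, 1000), 500)
  expect_equal(steady_state_auc24(3.17, 1250) * 3.17, 1250,
               tolerance = 1e-12)
  expect_error(steady_state_auc24(0, 1000), "positive")
})

test_that("regimen construction enforces its invariants", {
  expect_error(regimen(750, 12, infusion_duration = 13), "interval")
  expect_error(regimen(-10, 12), "positive")
  r <- regimen_for_daily_dose(1500)
  expect_equal(c(r$dose, r$interval), c(750, 12))
  r <- regimen_for_daily_dose(500)
  expect_equal(c(r$dose, r$interval), c(500, 24))
  r <- regimen_for_daily_dose(1000)
  expect_equal(c(r$dose, r$interval), c(500, 12))
})
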