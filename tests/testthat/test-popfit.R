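test_that("zero omega reduces the objective to the weighted LS deviance", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 6, seed = 14))
  m0 <- vcm_model(cl_terms = list(cov_term("clcr", 3.09, 0.63),
                                  cov_term("alb", 2.3, 0.22)),
                  omega_cl = 0, sigma = res_error("combined", 0.3, 0.1))
  ofv <- foce_objective(sim$data, m0)
  # manual fixed-effects deviance at eta = 0
  prep <- vancopk:::pk_subjects(sim$data)
  man <- sum(vapply(prep, function(s) {
    p <- individual_params(s$cov, eta = 0, model = m0)
    f <- concentration(p, data.frame(time = s$dose_t, amt = s$dose_amt,
                                     dur = s$dose_dur), s$t)
    v <- m0$sigma$add^2 + (m0$sigma$prop * f)^2
    sum(log(v) + (s$y - f)^2 / v + log(2 * pi))
  }, 0))
  expect_equal(ofv, man, tolerance = 1e-10)
})

test_that("the FOCE-I objective tracks the integrated marginal likelihood", {
  set.seed(7)
  m <- vcm_final_model()
  errs <- replicate(20, {
    eta <- rnorm(1, 0, 0.11)
    cov <- list(clcr = runif(1, 1.5, 5), alb = runif(1, 1.5, 3.5))
    p <- individual_params(cov, eta, m)
    sched <- vancopk:::dose_schedule(regimen_for_daily_dose(1000))
    tt <- c(98, 108, 120)
    f <- concentration(p, sched, tt)
    y <- pmax(f + sqrt(m$sigma$add^2 + (m$sigma$prop * f)^2) * rnorm(3),
              0.1)
    s <- list(y = y, t = tt, dose_t = sched$time, dose_amt = sched$amt,
              dose_dur = sched$dur, cov = cov)
    foce <- vancopk:::foce_subject_cpp(
      s$y, s$t, s$dose_t, s$dose_amt, s$dose_dur,
      vancopk:::cl_typical(m, cov), m$q, m$vc, m$vp, 0.11^2,
      m$sigma$add, m$sigma$prop)
    abs(foce$ofv - quad_ofv(s, m))
  })
  expect_lt(max(errs), 0.5)
  expect_lt(mean(errs), 0.2)
})

test_that("noise-free fixed-effects data are recovered to tolerance", {
  spec <- cohort_spec(n_subjects = 12, samples_per_subject = c(`4` = 1),
                      lloq = 0, seed = 31)
  truth <- vcm_model(cl_terms = list(cov_term("clcr", 3.09, 0.63),
                                     cov_term("alb", 2.3, 0.22)),
                     omega_cl = 0, sigma = res_error("additive", 1e-9))
  sim <- simulate_cohort(spec, truth = truth)
  init <- vcm_model(cl = 2.5, q = 4, vc = 40, vp = 45,
                    cl_terms = list(cov_term("clcr", 3.09, 0.4),
                                    cov_term("alb", 2.3, 0.1)),
                    omega_cl = 0.11,
                    sigma = res_error("additive", add = 0.01))
  f <- fit_population(sim$data, init = init, fix = c("sigma_add", "omega"),
                      se = FALSE)
  expect_true(f$converged)
  expect_equal(f$model$cl, 1.96, tolerance = 0.01)
  expect_equal(f$model$q, 4.86, tolerance = 0.01)
  expect_equal(f$model$vc, 31.78, tolerance = 0.01)
  expect_equal(f$model$vp, 53.64, tolerance = 0.01)
  expect_equal(f$model$cl_terms[[1]]$est, 0.63, tolerance = 0.01)
  expect_equal(f$model$cl_terms[[2]]$est, 0.22, tolerance = 0.01)
})

test_that("AIC identity holds and nesting never raises the optimum", {
  f <- fit40()
  expect_identical(f$aic, f$ofv + 2 * f$n_par)
  expect_identical(f$n_par, nrow(f$estimates))

  # dropping the albumin term (a nested submodel) cannot fit better
  sub <- f$model
  sub$cl_terms <- sub$cl_terms[1]
  f_sub <- fit_population(sim40()$data, init = sub, se = FALSE)
  expect_gte(f_sub$ofv, f$ofv - 1e-3)
})

test_that("repeated fits from perturbed inits agree", {
  f <- fit40()
  init2 <- f$model
  init2$cl <- f$model$cl * 1.3
  init2$vc <- f$model$vc * 0.8
  init2$cl_terms[[1]]$est <- 0.4
  f2 <- fit_population(sim40()$data, init = init2, se = FALSE)
  expect_equal(f2$model$cl, f$model$cl, tolerance = 1e-3)
  expect_equal(f2$ofv, f$ofv, tolerance = 1e-6)
})

test_that("typical clearance estimates are unbiased across cohorts", {
  cls <- vapply(1:10, function(r) {
    s <- simulate_cohort(cohort_spec(n_subjects = 40, seed = 400 + r))
    fit_population(s$data, init = vcm_final_model(), se = FALSE)$model$cl
  }, 0)
  expect_lt(abs(mean(cls) - 1.96) / 1.96, 0.05)
})

test_that("an irrelevant covariate rarely clears the 3.85 threshold", {
  truth <- vcm_model(cl_terms = list(cov_term("clcr", 3.09, 0.63)),
                     omega_cl = 0.11,
                     sigma = res_error("combined", 0.3, 0.10))
  rejections <- 0
  for (r in 1:10) {
    s <- simulate_cohort(cohort_spec(n_subjects = 30, seed = 100 + r),
                         truth = truth)
    f1 <- fit_population(s$data, init = vcm_model(
      cl_terms = list(cov_term("clcr", 3.09, 0.4)), omega_cl = 0.15,
      sigma = res_error("combined", 0.5, 0.15)), se = FALSE)
    m2 <- f1$model
    m2$cl_terms <- c(m2$cl_terms, list(cov_term("alb", 2.3, 0.05)))
    f2 <- fit_population(s$data, init = m2, se = FALSE)
    if (f1$ofv - f2$ofv > 3.85) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("shrinkage behaves across designs and degenerate cases", {
  expect_equal(shrinkage(rep(0, 20), 0.11), 100)
  expect_warning(s0 <- shrinkage(rnorm(10), 0), "undefined")
  expect_true(is.na(s0))
  expect_error(shrinkage(0.1, 0.11), "2 subjects")

  rich <- fit_population(simulate_cohort(
    cohort_spec(n_subjects = 30, samples_per_subject = c(`4` = 1),
                seed = 21))$data, init = vcm_final_model(), se = FALSE)
  sparse <- fit_population(simulate_cohort(
    cohort_spec(n_subjects = 30, samples_per_subject = c(`2` = 1),
                peak_fraction = 0, seed = 21))$data,
    init = vcm_final_model(), se = FALSE)
  expect_lt(rich$shrinkage_pct, 35)
  expect_gt(sparse$shrinkage_pct, rich$shrinkage_pct)
})

test_that("conditional weighted residuals are calibrated under the truth", {
  f <- fit40()
  cw <- cwres(f)
  expect_false(any(cw$flagged))
  expect_gte(mean(abs(cw$cwres) < 3), 0.99)
  expect_lt(abs(mean(cw$cwres)), 0.3)
})

test_that("duplicate observation times do not break the residuals", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 6, seed = 17))
  df <- as.data.frame(sim$data)
  dup <- df[df$EVID == 0, ][1, ]
  f <- fit_population(as_pk_dataset(rbind(df, dup, dup)),
                      init = vcm_final_model(), se = FALSE,
                      control = list(iter.max = 5))
  cw <- cwres(f)
  expect_true(all(is.finite(cw$cwres)))
})

test_that("a one-compartment fit to two-compartment data is detectable", {
  f2 <- fit40()
  init1 <- vcm_model(cl = 2, q = 1e-3, vc = 60, vp = 1,
                     cl_terms = list(cov_term("clcr", 3.09, 0.5),
                                     cov_term("alb", 2.3, 0.2)),
                     omega_cl = 0.15,
                     sigma = res_error("combined", 0.5, 0.15))
  f1 <- fit_population(sim40()$data, init = init1, fix = c("q", "vp"),
                       se = FALSE)
  expect_gt(f1$ofv - f2$ofv, 3.85)
  cw1 <- cwres(f1)
  cw2 <- cwres(f2)
  # systematic distribution-phase bias shows up in the peak residuals
  expect_gt(abs(mean(cw1$cwres[cw1$type == "peak"])),
            abs(mean(cw2$cwres[cw2$type == "peak"])))
})

test_that("the visual predictive check is self-consistent", {
  f <- fit40()
  v <- vpc(f, n_sim = 200, seed = 3)
  df <- as.data.frame(v)
  expect_gte(mean(df$observed >= df$sim_lo & df$observed <= df$sim_hi),
             0.9)
  # degenerate single replicate collapses the band to that replicate
  v1 <- vpc(f, n_sim = 1, seed = 3)
  expect_true(all(v1$sim_lo == v1$sim_hi))
  expect_true(all(v1$sim_lo == v1$sim_med))
})

test_that("the bootstrap identity resample reproduces the point estimate", {
  f <- fit40()
  ids <- unique(sim40()$data$ID)
  b <- pk_bootstrap(f, indices = list(ids))
  expect_equal(b$n_failed, 0)
  expect_equal(b$summary$estimate, f$estimates$estimate, tolerance = 1e-3)
})

test_that("stepwise selection finds the generating covariate and no more", {
  truth <- vcm_model(cl_terms = list(cov_term("clcr", 3.09, 0.63)),
                     omega_cl = 0.11,
                     sigma = res_error("combined", 0.3, 0.10))
  sim <- simulate_cohort(cohort_spec(n_subjects = 50, seed = 41),
                         truth = truth)
  base <- vcm_model(cl_terms = list(), omega_cl = 0.15,
                    sigma = res_error("combined", 0.5, 0.15))
  sw <- stepwise_select(sim$data, base = base,
                        cl_candidates = c("clcr", "alb"),
                        vc_candidates = character())
  picked <- vapply(sw$model$cl_terms, `[[`, "", "cov")
  expect_identical(picked, "clcr")
  expect_true(all(c("forward", "backward") %in% sw$path$action))
  expect_true(all(sw$path$aic == sw$path$ofv + 2 * sw$path$n_par,
                  na.rm = TRUE))

  # null case: no candidate clears the threshold, base model returned
  truth0 <- vcm_model(cl_terms = list(), omega_cl = 0.11,
                      sigma = res_error("combined", 0.3, 0.10))
  s0 <- simulate_cohort(cohort_spec(n_subjects = 30, seed = 51),
                        truth = truth0)
  sw0 <- stepwise_select(s0$data, base = base, cl_candidates = "alb",
                         vc_candidates = character())
  expect_length(sw0$model$cl_terms, 0)
  expect_equal(sum(sw0$path$accepted[sw0$path$action == "forward"]), 0)
})
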