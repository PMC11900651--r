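test_that("generated covariates respect bounds and the BMI constraint", {
  cov <- generate_covariates(cohort_spec(seed = 2))
  expect_equal(nrow(cov), 159)
  expect_true(all(cov$age >= 75 & cov$age <= 99))
  expect_true(all(cov$weight >= 26 & cov$weight <= 70))
  expect_true(all(cov$scr >= 0.22 & cov$scr <= 3.00))
  expect_true(all(cov$alb >= 1.2 & cov$alb <= 4.2))
  expect_true(all(cov$bmi < 25))
  expect_true(all(c("clcr", "clcr_ml_min", "egfr", "female") %in% names(cov)))
  expect_equal(cov$clcr, ml_min_to_l_h(cov$clcr_ml_min))

  # empty cohort
  expect_equal(nrow(generate_covariates(cohort_spec(n_subjects = 0))), 0)

  # infeasible weight/height vs BMI cap is rejected up front
  expect_error(generate_covariates(
    cohort_spec(weight = c(90, 80, 100), height = c(150, 140, 160))),
    "infeasible")
})

test_that("covariate medians approach their targets as n grows", {
  cov <- generate_covariates(cohort_spec(n_subjects = 2000, seed = 3))
  expect_lt(abs(median(cov$age) - 84), 2)
  expect_lt(abs(median(cov$weight) - 47), 3)
  expect_lt(abs(median(cov$scr) - 0.64), 0.06)
  expect_lt(abs(median(cov$alb) - 2.3), 0.15)
  expect_lt(abs(mean(cov$sex == "male") - 0.579), 0.04)
})

test_that("cohort generation is deterministic under a fixed seed", {
  s1 <- simulate_cohort(cohort_spec(n_subjects = 15, seed = 5))
  s2 <- simulate_cohort(cohort_spec(n_subjects = 15, seed = 5))
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$regimens, s2$regimens)
  expect_identical(as.data.frame(s1$data), as.data.frame(s2$data))
})

test_that("daily doses of 1000 mg or more are split twice daily", {
  cov <- generate_covariates(cohort_spec(n_subjects = 300, seed = 6))
  reg <- generate_regimens(cov, cohort_spec(n_subjects = 300, seed = 6))
  split <- reg$daily_dose >= 1000
  expect_true(all(reg$interval[split] == 12))
  expect_true(all(reg$dose_per_admin[split] == reg$daily_dose[split] / 2))
  expect_true(all(reg$interval[!split] == 24))
  expect_true(all(reg$dose_per_admin[!split] == reg$daily_dose[!split]))
  expect_true(all(reg$daily_dose %in% cohort_spec()$dose_levels))
})

test_that("sampling structure matches the cohort design", {
  sim <- fixture("sim_counts", simulate_cohort(cohort_spec(seed = 8)))
  obs <- sim$data[sim$data$EVID == 0, ]
  # about 417 samples, about 65 of them peaks (binomial variation)
  expect_gt(nrow(obs), 370)
  expect_lt(nrow(obs), 465)
  expect_gt(sum(obs$TYPE == "peak"), 40)
  expect_lt(sum(obs$TYPE == "peak"), 90)
  expect_true(all(obs$TYPE %in% c("peak", "trough")))
  # 2-4 samples per subject
  counts <- table(obs$ID)
  expect_true(all(counts >= 2 & counts <= 4))
  # BLQ flags exactly the observations below the limit of quantitation
  expect_equal(obs$BLQ, as.integer(obs$DV < 2.5))
})

test_that("noise-free observations equal the model predictions", {
  spec <- cohort_spec(n_subjects = 8, lloq = 0, seed = 9)
  truth <- vcm_model(omega_cl = 0, omega_type = "fixed_offset",
                     cl_terms = list(cov_term("clcr", 3.09, 0.63),
                                     cov_term("alb", 2.3, 0.22)),
                     sigma = res_error("additive", add = 1e-12))
  sim <- simulate_cohort(spec, truth = truth)
  obs <- sim$data[sim$data$EVID == 0, ]
  for (id in unique(obs$ID)) {
    cov <- sim$cohort[sim$cohort$id == id, ]
    p <- individual_params(cov, eta = 0)
    reg <- sim$regimens[sim$regimens$id == id, ]
    sched <- vancopk:::dose_schedule(vancopk:::regimen_from_row(reg))
    f <- concentration(p, sched, obs$TIME[obs$ID == id])
    expect_equal(obs$DV[obs$ID == id], f, tolerance = 1e-9)
  }
  # no below-LOQ flags when the limit is zero
  expect_true(all(obs$BLQ == 0))
})

test_that("proportional residual noise reproduces its generating CV", {
  spec <- cohort_spec(n_subjects = 120, samples_per_subject = c(`4` = 1),
                      lloq = 0, seed = 10)
  truth <- vcm_model(omega_cl = 0, omega_type = "fixed_offset",
                     cl_terms = list(cov_term("clcr", 3.09, 0.63),
                                     cov_term("alb", 2.3, 0.22)),
                     sigma = res_error("proportional", prop = 0.10))
  sim <- simulate_cohort(spec, truth = truth)
  obs <- sim$data[sim$data$EVID == 0, ]
  rel <- unlist(lapply(unique(obs$ID), function(id) {
    cov <- sim$cohort[sim$cohort$id == id, ]
    reg <- sim$regimens[sim$regimens$id == id, ]
    sched <- vancopk:::dose_schedule(vancopk:::regimen_from_row(reg))
    f <- concentration(individual_params(cov, eta = 0), sched,
                       obs$TIME[obs$ID == id])
    obs$DV[obs$ID == id] / f - 1
  }))
  expect_lt(abs(sd(rel) - 0.10), 0.015)
})
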