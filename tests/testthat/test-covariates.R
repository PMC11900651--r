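test_that("anthropometric and renal equations evaluate correctly", {
  expect_equal(bmi(47, 158), 47 / 1.58^2, tolerance = 1e-12)
  expect_equal(round(bmi(47, 158), 2), 18.83)
  expect_equal(bmi(25, 100), 25)
  expect_error(bmi(0, 160), "positive")

  expect_equal(cockcroft_gault(40, 72, 1.0, "male"), 100)
  expect_equal(cockcroft_gault(40, 72, 1.0, "female"), 85)
  expect_equal(round(cockcroft_gault(84, 47, 0.64, "male"), 1), 57.1)
  expect_error(cockcroft_gault(141, 60, 1, "male"), "140")

  expect_equal(round(egfr_japanese(1.0, 60, "male"), 1),
               round(194 * 60^-0.287, 1))
  expect_equal(egfr_japanese(1.0, 60, "female"),
               0.739 * egfr_japanese(1.0, 60, "male"))
  expect_equal(egfr_japanese(2.0, 60, "male"),
               egfr_japanese(1.0, 60, "male") * 2^-1.094)
  # unadjusted variant scales by DuBois BSA / 1.73
  expect_equal(egfr_japanese(1, 60, "male", bsa_adjusted = FALSE,
                             weight = 47, height = 158) /
                 egfr_japanese(1, 60, "male"),
               0.007184 * 47^0.425 * 158^0.725 / 1.73)
})

test_that("unit conversion round-trips exactly", {
  x <- c(9.7, 51.5, 121.2)
  expect_equal(l_h_to_ml_min(ml_min_to_l_h(x)), x, tolerance = 1e-12)
  expect_equal(ml_min_to_l_h(51.5), 3.09)
})

test_that("the clearance covariate model reproduces its published values", {
  expect_equal(round(predict_clearance(5.1, 1.5, eta = 0.11), 2), 2.73)
  expect_equal(round(predict_clearance(5.1, 3.5, eta = 0.11), 2), 3.29)
  expect_equal(predict_clearance(3.09, 2.3), 1.96)
  expect_equal(predict_clearance(2.4, 1.5),
               1.96 * (2.4 / 3.09)^0.63 * (1.5 / 2.3)^0.22,
               tolerance = 1e-12)
  expect_equal(round(predict_clearance(2.4, 1.5), 3), 1.522)
  expect_error(predict_clearance(-1, 2), "positive")

  # exp(eta) structure and exact power-law homogeneity
  expect_equal(predict_clearance(2.4, 2.0, eta = log(2)),
               2 * predict_clearance(2.4, 2.0))
  expect_equal(predict_clearance(3 * 2.4, 2.0),
               3^0.63 * predict_clearance(2.4, 2.0))
})

test_that("clearance is monotone in its covariates", {
  grid <- expand.grid(clcr = seq(0.6, 7, length.out = 8),
                      alb = seq(1.2, 4.2, length.out = 8))
  cl <- predict_clearance(grid$clcr, grid$alb)
  for (a in unique(grid$alb)) {
    expect_true(all(diff(cl[grid$alb == a]) > 0))
  }
  for (c_ in unique(grid$clcr)) {
    expect_true(all(diff(cl[grid$clcr == c_]) > 0))
  }
})

test_that("individual parameters combine clearance with fixed volumes", {
  p <- individual_params(list(clcr = 3.09, alb = 2.3))
  expect_equal(c(p$cl, p$q, p$vc, p$vp), c(1.96, 4.86, 31.78, 53.64))
  p2 <- individual_params(list(clcr = 3.09, alb = 2.3), eta = log(2))
  expect_equal(p2$cl, 2 * 1.96)
  expect_equal(c(p2$q, p2$vc, p2$vp), c(4.86, 31.78, 53.64))
})

test_that("model specifications round-trip through YAML losslessly", {
  m <- vcm_model(name = "alt", cl = 2.5, q = 3.1, vc = 40, vp = 60,
                 cl_terms = list(cov_term("clcr", 3.0, 0.7),
                                 cov_term("female", est = -0.1,
                                          type = "factor")),
                 omega_cl = 0.2, omega_type = "variance",
                 sigma = res_error("proportional", prop = 0.15))
  f <- tempfile(fileext = ".yaml")
  write_model_yaml(m, f)
  m2 <- read_model_yaml(f)
  expect_equal(m2, m)
  # the built-in default round-trips too
  write_model_yaml(vcm_final_model(), f)
  expect_equal(read_model_yaml(f), vcm_final_model())
})
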