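test_that("MIC sampling honors the distribution", {
  # degenerate point mass (including a level > 1, where index/value
  # confusion would show)
  expect_true(all(sample_mic(mic_distribution(2.0, 1), 50, seed = 1) == 2))
  # default distribution frequencies at n = 15000
  draws <- sample_mic(mic_distribution(), 15000, seed = 2)
  expect_lt(abs(mean(draws == 1.0) - 0.793), 0.01)
  expect_lt(abs(mean(draws == 0.5) - 0.116), 0.01)
  expect_true(all(draws %in% c(0.25, 0.5, 1, 2)))
  # invalid probabilities rejected
  expect_error(mic_distribution(c(0.5, 1), c(0.4, 0.5)), "sum to 1")
})

test_that("risk classes split at 10% and 25%", {
  expect_identical(risk_class(0.05), "mild")
  expect_identical(risk_class(0.10), "moderate")
  expect_identical(risk_class(0.25), "moderate")
  expect_identical(risk_class(0.30), "severe")
  expect_error(risk_class(1.2))
})

test_that("Monte-Carlo PTA agrees with the closed-form oracle", {
  cells <- expand.grid(dose = c(500, 750, 1000, 1500),
                       clcr = c(1.2, 2.4, 4.2), alb = c(1.5, 2.5, 3.5))
  for (i in seq_len(nrow(cells))) {
    o <- pta_oracle(cells$dose[i], cells$clcr[i], cells$alb[i])
    s <- simulate_pta(cells$dose[i], cells$clcr[i], cells$alb[i],
                      n_sim = 15000, seed = 30 + i)
    tol <- 3 * sqrt(max(o$pta * (1 - o$pta), 1e-6) / 15000)
    expect_lte(abs(s$pta - o$pta), tol + 1e-12)
    expect_lt(abs(s$p_auc_gt_600 - o$p_auc_gt_600), 0.02)
    expect_identical(s$risk, risk_class(s$p_auc_gt_600))
  }
})

test_that("the reference cell reproduces its published operating point", {
  # CLcr 2.4 L/h (40 mL/min), Alb 1.5 g/dL, 750 mg/day
  o <- pta_oracle(750, 2.4, 1.5)
  expect_equal(o$pta, 0.887, tolerance = 0.001)
  expect_equal(o$p_auc_gt_600, 0.037, tolerance = 0.01)
  s <- simulate_pta(750, 2.4, 1.5, seed = 77)
  expect_identical(s$risk, "mild")
})

test_that("omega interpretations change the simulation correctly", {
  m_var <- vcm_final_model(omega_type = "variance")
  o <- pta_oracle(750, 2.4, 1.5, model = m_var)
  # variance 0.11 means SD sqrt(0.11)
  mic <- mic_distribution()
  cl <- predict_clearance(2.4, 1.5)
  byhand <- sum(mic$prob * pnorm(log(750 / (400 * mic$support * cl)) /
                                   sqrt(0.11)))
  expect_equal(o$pta, byhand, tolerance = 1e-12)

  m_off <- vcm_model(omega_cl = 0.11, omega_type = "fixed_offset",
                     cl_terms = vcm_final_model()$cl_terms)
  o2 <- pta_oracle(2000, 2.4, 1.5, model = m_off)
  expect_true(all(o2$pta %in% c(0.001, 0.117, 0.910, 1)))
})

test_that("PTA is monotone in dose and MIC shift under shared draws", {
  doses <- c(250, 500, 750, 1000, 1250, 1500, 2000, 2500, 3000)
  ptas <- vapply(doses, function(d)
    simulate_pta(d, 2.4, 2.0, seed = 9)$pta, 0)
  expect_true(all(diff(ptas) >= 0))
  # shifting the whole MIC distribution upward cannot raise PTA
  up <- mic_distribution(c(0.5, 1, 2, 4), c(0.001, 0.116, 0.793, 0.090))
  p_up <- simulate_pta(1000, 2.4, 2.0, mic = up, seed = 9)$pta
  p_def <- simulate_pta(1000, 2.4, 2.0, seed = 9)$pta
  expect_lte(p_up, p_def)
})

test_that("optimal dose search matches its published cells", {
  od <- optimal_dose(clcr = 2.4, alb = 1.5, n_sim = 15000, seed = 13)
  expect_equal(od$dose, 750)
  od2 <- optimal_dose(clcr = 2.4, alb = 3.0, n_sim = 15000, seed = 13)
  expect_equal(od2$dose, 1000)
  # vacuous threshold returns the smallest dose
  od0 <- optimal_dose(clcr = 2.4, alb = 1.5, threshold = 0,
                      n_sim = 2000, seed = 13)
  expect_equal(od0$dose, 250)
  expect_error(optimal_dose(clcr = 2.4, alb = 1.5, threshold = 1),
               "threshold")
})

test_that("the nomogram is consistent, monotone and reproducible", {
  # degenerate one-cell grid equals the plain dose search with the same
  # draw stream
  n1 <- build_nomogram(alb_grid = 2.0, clcr_grid = 2.4, n_sim = 5000,
                       seed = 21)
  od <- optimal_dose(clcr = 2.4, alb = 2.0, n_sim = 5000,
                     draws = vancopk:::pta_draws(
                       5000, mic_distribution(),
                       vancopk:::derive_seed(21, "nomogram")))
  expect_equal(n1$cells$dose, od$dose)

  nom <- build_nomogram(n_sim = 4000, seed = 22)
  m <- as.matrix(nom)
  # doses never decrease along increasing creatinine clearance
  for (r in seq_len(nrow(m))) expect_true(all(diff(m[r, ]) >= 0))
  expect_true(all(nom$cells$risk %in% c("mild", "moderate", "severe")))
  # bit-reproducible under the same seed
  nom2 <- build_nomogram(n_sim = 4000, seed = 22)
  expect_identical(nom$cells, nom2$cells)
})

test_that("dose ranges over the clearance grid hit the published extremes", {
  r <- dose_range_over_cl_grid(n_sim = 15000, seed = 4)
  expect_equal(r$min_dose, 250)
  expect_equal(r$max_dose, 2000)
  expect_true(all(diff(r$table$dose) >= 0))

  rd <- dose_range_over_cl_grid(mode = "deterministic")
  expect_equal(rd$min_dose, 250)
  expect_equal(rd$max_dose, 2000)

  # fixed MIC 1.0, deterministic: strict boundary means 750/2.0 = 375
  # fails and 1000/2.0 = 500 succeeds
  r1 <- dose_range_over_cl_grid(cl_grid = 2.0, mode = "deterministic",
                                mic_fixed = 1.0)
  expect_equal(r1$table$dose, 1000)
})
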