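# Lazily computed, cached fixtures shared across test files. Everything
# is generated in code under fixed seeds; nothing is read from disk.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

theta_ref <- function() pk_params(cl = 1.96, q = 4.86, vc = 31.78,
                                  vp = 53.64)

sim40 <- function() fixture("sim40", simulate_cohort(
  cohort_spec(n_subjects = 40, seed = 11)))

fit40 <- function() fixture("fit40", fit_population(
  sim40()$data, init = vcm_final_model(), se = FALSE))

# MAP reference clearances for a simulated cohort (the validation
# harness: generating model injected as the Bayesian prior).
map_reference <- function(sim, prior = vcm_final_model()) {
  prep <- vancopk:::pk_subjects(sim$data)
  ref <- vapply(prep, function(s) {
    reg <- sim$regimens[sim$regimens$id == s$id, ]
    map_fit(data.frame(time = s$t, dv = s$y),
            data.frame(time = s$dose_t, amt = s$dose_amt, dur = s$dose_dur),
            s$cov, prior = prior, daily_dose = reg$daily_dose)$cl
  }, 0)
  ids <- vapply(prep, `[[`, 0, "id")
  list(cohort = sim$cohort[match(ids, sim$cohort$id), ], cl = ref)
}
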