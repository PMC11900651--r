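# Independent numerical oracles used to cross-check the analytic and
# approximate computations.

# Two-compartment concentrations by ODE integration (deSolve::lsoda).
ode_conc <- function(p, sched, times, rtol = 1e-11) {
  d <- disposition_constants(p)
  rhs <- function(t, y, parms) {
    infusing <- t > sched$time & t <= sched$time + sched$dur
    inf <- sum(ifelse(infusing, sched$amt / sched$dur, 0))
    list(c(inf - (d$k10 + d$k12) * y[1] + d$k21 * y[2],
           d$k12 * y[1] - d$k21 * y[2]))
  }
  sol <- deSolve::lsoda(c(0, 0), c(0, times), rhs, parms = NULL,
                        rtol = rtol, atol = rtol)
  sol[-1, 2] / p$vc
}

# -2 log marginal likelihood of one subject by adaptive quadrature over
# the clearance random effect.
quad_ofv <- function(s, model) {
  om <- vancopk:::omega_sd(model)
  cl_pop <- vancopk:::cl_typical(model, s$cov)
  vc_pop <- vancopk:::vc_typical(model, s$cov)
  sched <- data.frame(time = s$dose_t, amt = s$dose_amt, dur = s$dose_dur)
  lik <- function(eta) {
    vapply(eta, function(e) {
      p <- pk_params(cl_pop * exp(e), model$q, vc_pop, model$vp)
      f <- concentration(p, sched, s$t)
      v <- model$sigma$add^2 + (model$sigma$prop * f)^2
      exp(sum(dnorm(s$y, f, sqrt(v), log = TRUE))) * dnorm(e, 0, om)
    }, 0)
  }
  -2 * log(integrate(lik, -1.5, 1.5, rel.tol = 1e-10)$value)
}
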