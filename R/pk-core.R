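#' Individual two-compartment parameters
#'
#' @param cl clearance (L/h).
#' @param q intercompartmental clearance (L/h); `q = 0` collapses to a
#'   one-compartment model.
#' @param vc central volume of distribution (L).
#' @param vp peripheral volume of distribution (L).
#' @return an object of class `pk_params`.
#' @export
pk_params <- function(cl, q, vc, vp) {
  stop_if_not_positive(c(cl, vc, vp), "cl/vc/vp")
  if (any(q < 0)) stop("`q` must be >= 0")
  structure(list(cl = cl, q = q, vc = vc, vp = vp), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> CL %.4g L/h, Q %.4g L/h, Vc %.4g L, Vp %.4g L\n",
              x$cl, x$q, x$vc, x$vp))
  invisible(x)
}

#' Disposition micro- and macro-constants
#'
#' Standard reparameterization of the two-compartment model:
#' `k10 = CL/Vc`, `k12 = Q/Vc`, `k21 = Q/Vp`; `alpha` and `beta` are the
#' hybrid rate constants satisfying `alpha * beta = k10 * k21` and
#' `alpha + beta = k10 + k12 + k21`.
#'
#' @param p a [pk_params()] object.
#' @return list with `k10`, `k12`, `k21`, `alpha`, `beta` and a
#'   `degenerate` flag (`TRUE` when `q = 0`, i.e. the one-compartment
#'   limit `alpha = k10`, `beta = 0`).
#' @export
disposition_constants <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  k10 <- p$cl / p$vc
  k12 <- p$q / p$vc
  k21 <- p$q / p$vp
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  list(k10 = k10, k12 = k12, k21 = k21,
       alpha = (s + disc) / 2, beta = (s - disc) / 2,
       degenerate = p$q == 0)
}

#' Intermittent intravenous infusion regimen
#'
#' @param dose dose per administration (mg).
#' @param interval dosing interval (h).
#' @param infusion_duration length of the zero-order infusion (h); must
#'   not exceed the interval. `0` is an instantaneous bolus.
#' @param n_doses number of administrations.
#' @param start time of the first dose (h).
#' @return an object of class `regimen`.
#' @export
regimen <- function(dose, interval = 12, infusion_duration = 1,
                    n_doses = 10, start = 0) {
  stop_if_not_positive(dose, "dose")
  stop_if_not_positive(interval, "interval")
  if (infusion_duration < 0 || infusion_duration > interval) {
    stop("`infusion_duration` must lie in [0, interval]")
  }
  stopifnot(n_doses >= 1, start >= 0)
  structure(list(dose = dose, interval = interval,
                 infusion_duration = infusion_duration,
                 n_doses = n_doses, start = start),
            class = "regimen")
}

#' Regimen implied by a daily maintenance dose
#'
#' Daily doses of 1000 mg or more are split into two administrations
#' 12 hours apart; smaller daily doses are given once daily.
#'
#' @param daily_dose total daily dose (mg).
#' @param days days of therapy.
#' @param infusion_duration infusion length per administration (h).
#' @param split_threshold daily dose (mg) at or above which dosing is
#'   twice daily.
#' @return a [regimen()].
#' @examples
#' regimen_for_daily_dose(1500)  # 750 mg every 12 h
#' regimen_for_daily_dose(500)   # 500 mg every 24 h
#' @export
regimen_for_daily_dose <- function(daily_dose, days = 5,
                                   infusion_duration = 1,
                                   split_threshold = 1000) {
  stop_if_not_positive(daily_dose, "daily_dose")
  if (daily_dose >= split_threshold) {
    regimen(dose = daily_dose / 2, interval = 12,
            infusion_duration = infusion_duration, n_doses = 2 * days)
  } else {
    regimen(dose = daily_dose, interval = 24,
            infusion_duration = infusion_duration, n_doses = days)
  }
}

# Expand a regimen into an event schedule (dose start times, amounts,
# durations).
dose_schedule <- function(reg) {
  stopifnot(inherits(reg, "regimen"))
  data.frame(time = reg$start + (seq_len(reg$n_doses) - 1) * reg$interval,
             amt = rep(reg$dose, reg$n_doses),
             dur = rep(reg$infusion_duration, reg$n_doses))
}

#' Central concentration under multiple infusions
#'
#' Analytic superposition of per-dose zero-order-infusion bi-exponential
#' solutions of the two-compartment model; times before the first dose
#' return 0.
#'
#' @param p a [pk_params()] object.
#' @param reg a [regimen()] or a data.frame schedule with columns
#'   `time`, `amt`, `dur`.
#' @param t times (h) at which to evaluate the concentration.
#' @return concentrations (mg/L).
#' @examples
#' p <- pk_params(1.96, 4.86, 31.78, 53.64)
#' concentration(p, regimen(750, 12, 1, n_doses = 10), c(1, 12, 95, 96))
#' @export
concentration <- function(p, reg, t) {
  stopifnot(inherits(p, "pk_params"))
  sched <- if (inherits(reg, "regimen")) dose_schedule(reg) else reg
  if (any(t < 0)) stop("`t` must be >= 0")
  conc2cmt_cpp(as.double(t), as.double(sched$time), as.double(sched$amt),
               as.double(sched$dur), p$cl, p$q, p$vc, p$vp)
}

#' Steady-state 24-hour area under the curve
#'
#' For a linear, cleared drug the steady-state AUC over 24 h is
#' `daily_dose / CL` regardless of how the daily dose is split across
#' administrations.
#'
#' @param cl clearance (L/h).
#' @param daily_dose total daily dose (mg).
#' @return AUCss over 24 h (ug.h/mL).
#' @examples
#' steady_state_auc24(1.96, 1500)  # 765.3
#' @export
steady_state_auc24 <- function(cl, daily_dose) {
  stop_if_not_positive(cl, "cl")
  daily_dose / cl
}

#' Steady-state concentration within a dosing interval
#'
#' Closed-form multiple-infusion solution at steady state (geometric
#' accumulation of the per-dose exponential terms); `t` is the time after
#' the start of an infusion, in `[0, interval]`.
#'
#' @param p a [pk_params()] object.
#' @param reg a [regimen()] (its `n_doses` is ignored: accumulation is
#'   taken to its infinite-dose limit).
#' @param t time after the start of a steady-state dose (h).
#' @return concentrations (mg/L).
#' @export
steady_state_concentration <- function(p, reg, t) {
  stopifnot(inherits(p, "pk_params"), inherits(reg, "regimen"))
  d <- disposition_constants(p)
  la <- d$alpha
  lb <- max(d$beta, la * 1e-9)  # clamp the repeated/degenerate root
  gap <- la - lb
  Aa <- (la - d$k21) / (p$vc * gap)
  Ab <- (d$k21 - lb) / (p$vc * gap)
  Tinf <- reg$infusion_duration
  tau <- reg$interval
  R <- if (Tinf > 0) reg$dose / Tinf else 0
  term <- function(A, lam) {
    if (A == 0 || lam <= 0) return(rep(0, length(t)))
    if (Tinf > 0) {
      cur <- A * R / lam * (1 - exp(-lam * pmin(t, Tinf))) *
        exp(-lam * pmax(t - Tinf, 0))
      res <- A * R / lam * (1 - exp(-lam * Tinf)) * exp(-lam * (t - Tinf)) *
        exp(-lam * tau) / (1 - exp(-lam * tau))
    } else {
      cur <- A * reg$dose * exp(-lam * t)
      res <- A * reg$dose * exp(-lam * t) * exp(-lam * tau) /
        (1 - exp(-lam * tau))
    }
    cur + res
  }
  term(Aa, la) + term(Ab, lb)
}

#' Steady-state peak and trough concentrations
#'
#' Peak is evaluated at the end of the infusion (optionally at a
#' configurable delay after it, matching a therapeutic drug monitoring
#' draw); trough at the end of the dosing interval, immediately before the
#' next dose.
#'
#' @param p a [pk_params()] object.
#' @param reg a [regimen()].
#' @param peak_delay time after the end of infusion at which the peak is
#'   read (h).
#' @return list with `peak` and `trough` (mg/L); `trough <= peak`.
#' @export
steady_state_peak_trough <- function(p, reg, peak_delay = 0) {
  tpk <- min(reg$infusion_duration + peak_delay, reg$interval)
  cc <- steady_state_concentration(p, reg, c(tpk, reg$interval))
  list(peak = cc[1], trough = cc[2])
}
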