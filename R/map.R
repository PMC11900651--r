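#' MAP Bayesian estimate of individual clearance
#'
#' Maximizes the posterior of the clearance random effect — residual
#' likelihood of the observed (typically peak/trough) concentrations times
#' the normal eta prior of the population model — and returns the
#' individual clearance, the steady-state 24-h AUC under the subject's
#' regimen, and the daily dose (on the 250-mg grid) targeting an AUCss of
#' 500 ug.h/mL. This is the reference-value generator of the validation
#' workflow: therapeutic drug monitoring software computes "Bayesian"
#' clearance exactly this way.
#'
#' @param obs data.frame of observations with columns `time` (h) and `dv`
#'   (mg/L); zero rows fall back to the prior mode (`eta = 0`) with
#'   `prior_only = TRUE`.
#' @param reg the subject's [regimen()] (or schedule data.frame, in which
#'   case `daily_dose` must be given).
#' @param cov subject covariates (list or one-row data.frame with the
#'   covariates the prior model needs, e.g. `clcr`, `alb`).
#' @param prior population [vcm_model()] acting as the Bayesian prior.
#' @param flat_prior drop the eta penalty (unpenalized least squares on
#'   the same observations).
#' @param target_auc AUCss target for the dose recommendation.
#' @param daily_dose total daily dose (mg); derived from `reg` when it is
#'   a [regimen()].
#' @return object of class `map_estimate`: `eta_hat`, `params`
#'   ([pk_params()]), `cl`, `auc24_ss`, `recommended_dose`, `prior_only`.
#' @examples
#' reg <- regimen_for_daily_dose(1000)
#' obs <- data.frame(time = c(98, 108), dv = c(25, 12))
#' map_fit(obs, reg, list(clcr = 2.4, alb = 2.5))
#' @export
map_fit <- function(obs, reg, cov, prior = vcm_final_model(),
                    flat_prior = FALSE, target_auc = 500,
                    daily_dose = NULL) {
  stopifnot(inherits(prior, "vcm_model"))
  if (inherits(reg, "regimen")) {
    sched <- dose_schedule(reg)
    if (is.null(daily_dose)) daily_dose <- reg$dose * 24 / reg$interval
  } else {
    sched <- reg
    if (is.null(daily_dose)) {
      stop("`daily_dose` is required when `reg` is a raw schedule")
    }
  }
  fixed_off <- prior$omega_type == "fixed_offset"
  cl_pop <- cl_typical(prior, cov) * if (fixed_off) exp(prior$omega_cl) else 1
  vc_pop <- vc_typical(prior, cov)

  prior_only <- is.null(obs) || nrow(obs) == 0
  if (prior_only) {
    eta <- 0
  } else {
    om2 <- if (flat_prior) Inf else if (fixed_off) 0 else omega_sd(prior)^2
    res <- foce_subject_cpp(obs$dv, obs$time, sched$time, sched$amt,
                            sched$dur, cl_pop, prior$q, vc_pop, prior$vp,
                            om2, prior$sigma$add, prior$sigma$prop)
    eta <- res$eta
  }
  cl <- cl_pop * exp(eta)
  structure(list(eta_hat = eta,
                 params = pk_params(cl, prior$q, vc_pop, prior$vp),
                 cl = cl,
                 auc24_ss = steady_state_auc24(cl, daily_dose),
                 recommended_dose = dose_for_target_auc(cl, target_auc),
                 daily_dose = daily_dose,
                 prior_only = prior_only),
            class = "map_estimate")
}

#' @export
print.map_estimate <- function(x, ...) {
  cat(sprintf(paste0("MAP estimate: eta %.4f, CL %.3f L/h, AUCss %.1f",
                     " ug.h/mL at %g mg/day%s\n"),
              x$eta_hat, x$cl, x$auc24_ss, x$daily_dose,
              if (x$prior_only) " (prior only)" else ""))
  cat(sprintf("  dose for AUCss 500: %g mg/day\n", x$recommended_dose))
  invisible(x)
}

#' Daily dose achieving a target steady-state AUC
#'
#' `target_auc * CL` rounded to the nearest 250-mg multiple (ties round
#' up), with a 250-mg floor.
#'
#' @param cl clearance (L/h).
#' @param target_auc AUCss target (ug.h/mL), 500 by default.
#' @return daily dose (mg) on the 250-mg grid.
#' @examples
#' dose_for_target_auc(2.0)   # 1000
#' dose_for_target_auc(1.7)   # 850 -> 750
#' dose_for_target_auc(1.75)  # 875 -> 1000 (half up)
#' @export
dose_for_target_auc <- function(cl, target_auc = 500) {
  stop_if_not_positive(cl, "cl")
  round_to_step(target_auc * cl, 250)
}
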