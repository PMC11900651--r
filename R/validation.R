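#' Mean absolute error and mean squared error
#'
#' Predictive-performance metrics against reference values, with 95%
#' confidence intervals from the normal approximation on the per-subject
#' error summaries.
#'
#' @param pred,ref equal-length numeric vectors.
#' @param conf confidence level.
#' @return list with `mae`, `mae_ci`, `mse`, `mse_ci`, `n`.
#' @examples
#' mae_mse(c(1.5, 2.5), c(1.0, 3.0))  # mae 0.5, mse 0.25
#' @export
mae_mse <- function(pred, ref, conf = 0.95) {
  if (length(pred) != length(ref)) stop("`pred` and `ref` lengths differ")
  if (!length(pred)) stop("need at least one pair")
  z <- qnorm(1 - (1 - conf) / 2)
  ae <- abs(pred - ref)
  se2 <- (pred - ref)^2
  n <- length(ae)
  half <- function(x) if (n > 1) z * sd(x) / sqrt(n) else 0
  list(mae = mean(ae), mae_ci = mean(ae) + c(-1, 1) * half(ae),
       mse = mean(se2), mse_ci = mean(se2) + c(-1, 1) * half(se2),
       n = n)
}

#' Pearson correlation with Fisher-z interval
#'
#' Thin wrapper around [stats::cor.test()] returning the product-moment
#' estimate, its Fisher-z 95% confidence interval, and the p-value.
#' Zero-variance input yields `NA` with a warning rather than an error.
#'
#' @param x,y numeric vectors (length at least 3).
#' @return list with `r`, `ci`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y))
  ci <- if (!is.null(ct$conf.int)) as.double(ct$conf.int) else c(NA, NA)
  list(r = unname(ct$estimate), ci = ci, p = ct$p.value, n = length(x))
}

#' Head-to-head predictive performance of population models
#'
#' For each candidate model, the population-predicted clearance (typical
#' value at the subject's covariates, `eta = 0`) is compared with a
#' reference clearance per subject (in the intended workflow, the MAP
#' Bayesian estimate from peak/trough sampling). MAE and MSE are reported
#' for clearance and for the daily dose achieving an AUCss of 500
#' (both predicted and reference doses rounded to the 250-mg grid), in
#' two subgroups: all subjects aged 75+ and the subset with serum
#' creatinine below 0.6 mg/dL.
#'
#' @param cohort covariate data.frame (needs `age`, `scr`, and whatever
#'   the models' clearance terms reference, e.g. `clcr`, `alb`).
#' @param models named list of [vcm_model()] objects.
#' @param reference_cl per-subject reference clearances (L/h), aligned
#'   with `cohort` rows; `NA` entries are excluded pairwise.
#' @param subgroups named list of predicate functions on the cohort.
#' @param target_auc AUCss target for the dose comparison.
#' @return data.frame (class `vcm_validation`): one row per model,
#'   subgroup and metric with `value`, `ci_lo`, `ci_hi`, `n`.
#' @export
compare_models <- function(cohort, models, reference_cl,
                           subgroups = list(
                             "age>=75" = function(d) d$age >= 75,
                             "age>=75 & scr<0.6" =
                               function(d) d$age >= 75 & d$scr < 0.6),
                           target_auc = 500) {
  stopifnot(is.data.frame(cohort), length(reference_cl) == nrow(cohort))
  if (is.null(names(models))) {
    names(models) <- vapply(models, `[[`, "", "name")
  }
  ref_dose <- ifelse(is.na(reference_cl), NA,
                     dose_for_target_auc(pmax(reference_cl, 1e-6),
                                         target_auc))
  rows <- list()
  for (mn in names(models)) {
    pred_cl <- cl_typical(models[[mn]], cohort)
    pred_dose <- dose_for_target_auc(pred_cl, target_auc)
    for (sg in names(subgroups)) {
      keep <- subgroups[[sg]](cohort) & !is.na(reference_cl)
      n_excluded <- sum(subgroups[[sg]](cohort)) - sum(keep)
      if (n_excluded > 0) {
        message(sprintf("%s / %s: %d subject(s) without reference excluded",
                        mn, sg, n_excluded))
      }
      if (!any(keep)) next
      m_cl <- mae_mse(pred_cl[keep], reference_cl[keep])
      m_do <- mae_mse(pred_dose[keep], ref_dose[keep])
      add <- function(metric, val, ci) {
        rows[[length(rows) + 1]] <<- data.frame(
          model = mn, subgroup = sg, metric = metric, value = val,
          ci_lo = ci[1], ci_hi = ci[2], n = m_cl$n)
      }
      add("mae_cl", m_cl$mae, m_cl$mae_ci)
      add("mse_cl", m_cl$mse, m_cl$mse_ci)
      add("mae_dose", m_do$mae, m_do$mae_ci)
      add("mse_dose", m_do$mse, m_do$mse_ci)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vcm_validation", "data.frame")
  out
}
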