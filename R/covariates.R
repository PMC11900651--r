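#' Body mass index
#'
#' @param weight body weight (kg).
#' @param height height (cm).
#' @return BMI in kg/m^2.
#' @examples
#' bmi(47, 158)  # 18.83
#' @export
bmi <- function(weight, height) {
  stop_if_not_positive(weight, "weight")
  stop_if_not_positive(height, "height")
  weight / (height / 100)^2
}

#' Cockcroft-Gault creatinine clearance
#'
#' `CLcr = (140 - age) * weight / (72 * SCr)`, multiplied by 0.85 for
#' females. Returned in mL/min by default; `unit = "l_h"` applies the
#' 0.06 conversion used by the clearance model.
#'
#' @param age age (years), must be below 140.
#' @param weight body weight (kg).
#' @param scr serum creatinine (mg/dL).
#' @param sex `"male"`/`"female"` (or a 0/1 female indicator).
#' @param unit `"ml_min"` or `"l_h"`.
#' @return creatinine clearance estimate.
#' @examples
#' cockcroft_gault(84, 47, 0.64, "male")  # 57.1 mL/min
#' @export
cockcroft_gault <- function(age, weight, scr, sex, unit = c("ml_min", "l_h")) {
  unit <- match.arg(unit)
  stop_if_not_positive(scr, "scr")
  stop_if_not_positive(weight, "weight")
  if (any(age < 0) || any(age >= 140)) {
    stop("`age` must be in [0, 140) for the Cockcroft-Gault equation")
  }
  female <- sex_indicator(sex)
  out <- (140 - age) * weight / (72 * scr) * ifelse(female == 1, 0.85, 1)
  if (unit == "l_h") ml_min_to_l_h(out) else out
}

#' Japanese eGFR equation
#'
#' `eGFR = 194 * SCr^-1.094 * age^-0.287` (mL/min/1.73 m^2), times 0.739
#' for females. With `bsa_adjusted = FALSE` the value is rescaled by the
#' subject's DuBois body surface area relative to 1.73 m^2, which requires
#' `weight` and `height`.
#'
#' @param scr serum creatinine (mg/dL).
#' @param age age (years).
#' @param sex `"male"`/`"female"` (or 0/1 female indicator).
#' @param bsa_adjusted keep the 1.73 m^2 normalization (default) or
#'   rescale to the individual's body surface area.
#' @param weight,height needed when `bsa_adjusted = FALSE`.
#' @return eGFR (mL/min/1.73 m^2, or mL/min when unadjusted).
#' @examples
#' egfr_japanese(1.0, 60, "male")  # 59.9
#' @export
egfr_japanese <- function(scr, age, sex, bsa_adjusted = TRUE,
                          weight = NULL, height = NULL) {
  stop_if_not_positive(scr, "scr")
  stop_if_not_positive(age, "age")
  female <- sex_indicator(sex)
  out <- 194 * scr^(-1.094) * age^(-0.287) * ifelse(female == 1, 0.739, 1)
  if (!bsa_adjusted) {
    if (is.null(weight) || is.null(height)) {
      stop("`weight` and `height` are required when `bsa_adjusted = FALSE`")
    }
    out <- out * bsa_dubois(weight, height) / 1.73
  }
  out
}

# DuBois body surface area (m^2).
bsa_dubois <- function(weight, height) {
  0.007184 * weight^0.425 * height^0.725
}

# Normalize sex coding to a female indicator (1 = female).
sex_indicator <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    s <- tolower(as.character(sex))
    if (!all(s %in% c("male", "female"))) stop("sex must be 'male'/'female'")
    as.integer(s == "female")
  } else {
    if (!all(sex %in% c(0, 1))) stop("numeric sex must be 0 (male)/1 (female)")
    as.integer(sex)
  }
}

#' Predict typical or individual vancomycin clearance
#'
#' Evaluates the covariate model for clearance. Under the default
#' [vcm_final_model()] this is
#' `CL = 1.96 * (CLcr/3.09)^0.63 * (Alb/2.3)^0.22 * exp(eta)` with CLcr in
#' L/h and Alb in g/dL.
#'
#' @param clcr creatinine clearance (L/h).
#' @param alb serum albumin (g/dL).
#' @param eta clearance random effect on the log scale (0 for the typical
#'   subject).
#' @param model a [vcm_model()]; models whose clearance terms use other
#'   covariates can be evaluated through the `...` arguments.
#' @param ... further named covariates required by `model$cl_terms`.
#' @return clearance (L/h).
#' @examples
#' predict_clearance(5.1, 1.5, eta = 0.11)  # 2.73 L/h
#' predict_clearance(5.1, 3.5, eta = 0.11)  # 3.29 L/h
#' @export
predict_clearance <- function(clcr, alb, eta = 0, model = vcm_final_model(),
                              ...) {
  cov <- c(list(clcr = clcr, alb = alb), list(...))
  cl_typical(model, cov) * exp(eta)
}

#' Individual structural parameters from covariates
#'
#' Clearance comes from [predict_clearance()]; intercompartmental
#' clearance and the two volumes are the model's typical values (the final
#' model carries no random effects or covariates on them, though covariate
#' terms on Vc are honored when present).
#'
#' @param cov a list or one-row data.frame of covariates (needs whatever
#'   the model's terms reference, e.g. `clcr` and `alb`).
#' @param eta clearance random effect.
#' @param model a [vcm_model()].
#' @return a [pk_params()] object.
#' @examples
#' individual_params(list(clcr = 3.09, alb = 2.3))
#' @export
individual_params <- function(cov, eta = 0, model = vcm_final_model()) {
  pk_params(cl = cl_typical(model, cov) * exp(eta),
            q = model$q,
            vc = vc_typical(model, cov),
            vp = model$vp)
}

#' Derive anthropometric and renal-function covariates
#'
#' Adds `bmi` (kg/m^2), `clcr_ml_min`, `clcr` (L/h, the unit used by the
#' clearance model) and `egfr` columns to a covariate data.frame holding
#' `age`, `sex`, `weight`, `height`, `scr`, `alb`.
#'
#' @param df covariate data.frame.
#' @return `df` with derived columns.
#' @export
derive_covariates <- function(df) {
  df$female <- if (nrow(df)) sex_indicator(df$sex) else integer(0)
  df$bmi <- bmi(df$weight, df$height)
  df$clcr_ml_min <- cockcroft_gault(df$age, df$weight, df$scr, df$sex)
  df$clcr <- ml_min_to_l_h(df$clcr_ml_min)
  df$egfr <- egfr_japanese(df$scr, df$age, df$sex)
  df
}
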