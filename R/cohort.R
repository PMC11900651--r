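#' Specification of a virtual elderly cohort
#'
#' Defaults reproduce the modeling population: n = 159 patients aged 75+
#' with median (range) age 84 (75-99) years, weight 47 (26-70) kg, height
#' 158 (135-180) cm, serum creatinine 0.64 (0.22-3.00) mg/dL, albumin 2.3
#' (1.2-4.2) g/dL, 57.9% male, BMI below 25 kg/m^2, daily maintenance
#' doses of 250-3000 mg (band frequencies matched to the observed dose
#' distribution: 27.7% below 1000 mg, 67.9% at 1000-2000 mg, 4.4% above,
#' median 1500 mg), and about 417 concentration samples of which 65 are
#' peaks. Continuous covariates are drawn from log-normal distributions
#' whose median equals the cohort median, truncated to the observed range
#' by inverse-CDF sampling.
#'
#' @param n_subjects number of subjects.
#' @param age,weight,height,scr,alb length-3 vectors `(median, min, max)`.
#' @param male_fraction proportion of males.
#' @param bmi_max subjects are constrained to BMI strictly below this.
#' @param dose_levels candidate daily doses (mg, positive multiples of
#'   50).
#' @param dose_probs sampling probabilities for `dose_levels`.
#' @param samples_per_subject named probability vector over the number of
#'   concentration samples drawn per subject.
#' @param peak_fraction probability that a sample is a peak (default
#'   65/417).
#' @param days days of therapy (sampling occurs over the final days, near
#'   steady state).
#' @param infusion_duration infusion length (h).
#' @param peak_delay nominal peak draw time after end of infusion (h).
#' @param time_jitter half-width (h) of the uniform jitter applied to
#'   sampling times: peaks are drawn at `peak_delay +/- time_jitter`
#'   after the infusion ends and troughs up to `time_jitter` before the
#'   next dose, emulating the irregular draw times of real therapeutic
#'   drug monitoring (exact nominal times leave the distribution-phase
#'   parameters poorly identified). Set to 0 for exact nominal times.
#' @param lloq lower limit of quantitation of the assay (mg/L).
#' @param seed master seed for the simulate stage.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 159,
                        age = c(84, 75, 99),
                        weight = c(47, 26, 70),
                        height = c(158, 135, 180),
                        scr = c(0.64, 0.22, 3.00),
                        alb = c(2.3, 1.2, 4.2),
                        male_fraction = 0.579,
                        bmi_max = 25,
                        dose_levels = c(250, 500, 750, 1000, 1250, 1500,
                                        1750, 2000, 2500, 3000),
                        dose_probs = c(0.05, 0.10, 0.127, 0.10, 0.08, 0.35,
                                       0.06, 0.089, 0.028, 0.016),
                        samples_per_subject = c(`2` = 0.45, `3` = 0.48,
                                                `4` = 0.07),
                        peak_fraction = 65 / 417,
                        days = 5, infusion_duration = 1, peak_delay = 1,
                        time_jitter = 0.75, lloq = 2.5, seed = NULL) {
  rng <- function(v, what) {
    if (length(v) != 3 || v[2] > v[1] || v[1] > v[3]) {
      stop(sprintf("`%s` must be (median, min, max) with min <= median <= max",
                   what))
    }
    as.double(v)
  }
  if (n_subjects < 0) stop("`n_subjects` must be >= 0")
  if (male_fraction < 0 || male_fraction > 1 ||
      peak_fraction < 0 || peak_fraction > 1) {
    stop("proportions must lie in [0, 1]")
  }
  stop_if_not_positive(dose_levels, "dose_levels")
  if (any(dose_levels %% 50 != 0)) {
    stop("`dose_levels` must be multiples of 50 mg")
  }
  if (length(dose_probs) != length(dose_levels) ||
      abs(sum(dose_probs) - 1) > 1e-8) {
    stop("`dose_probs` must match `dose_levels` and sum to 1")
  }
  if (abs(sum(samples_per_subject) - 1) > 1e-8) {
    stop("`samples_per_subject` probabilities must sum to 1")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 age = rng(age, "age"), weight = rng(weight, "weight"),
                 height = rng(height, "height"), scr = rng(scr, "scr"),
                 alb = rng(alb, "alb"),
                 male_fraction = male_fraction, bmi_max = bmi_max,
                 dose_levels = dose_levels, dose_probs = dose_probs,
                 samples_per_subject = samples_per_subject,
                 peak_fraction = peak_fraction, days = days,
                 infusion_duration = infusion_duration,
                 peak_delay = peak_delay, time_jitter = time_jitter,
                 lloq = lloq, seed = seed),
            class = "cohort_spec")
}

# Truncated log-normal draw by inverse CDF: median at `med`, support
# [lo, hi]; sdlog spans the range at about +/- 3 sd on the log scale.
rlnorm_trunc <- function(n, med, lo, hi) {
  if (lo == hi) return(rep(lo, n))
  meanlog <- log(med)
  sdlog <- (log(hi) - log(lo)) / 6
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  qlnorm(plo + runif(n) * (phi - plo), meanlog, sdlog)
}

#' Generate baseline covariates for a virtual cohort
#'
#' Draws demographics and laboratory values per [cohort_spec()], jointly
#' resampling weight and height until every subject satisfies the BMI
#' constraint, and derives BMI, Cockcroft-Gault creatinine clearance (both
#' unit views) and eGFR.
#'
#' @param spec a [cohort_spec()].
#' @param seed overrides `spec$seed`.
#' @param max_attempts bound on BMI rejection rounds before the spec is
#'   declared infeasible.
#' @return covariate data.frame with one row per subject.
#' @export
generate_covariates <- function(spec = cohort_spec(), seed = spec$seed,
                                max_attempts = 1000) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (bmi(spec$weight[2], spec$height[3]) >= spec$bmi_max) {
    stop("infeasible spec: minimum weight at maximum height violates bmi_max")
  }
  n <- spec$n_subjects
  if (n == 0) {
    return(derive_covariates(data.frame(id = integer(), age = double(),
                                        sex = character(), weight = double(),
                                        height = double(), scr = double(),
                                        alb = double())[0, ]))
  }
  with_seed(derive_seed(seed, "covariates"), {
    age <- rlnorm_trunc(n, spec$age[1], spec$age[2], spec$age[3])
    scr <- rlnorm_trunc(n, spec$scr[1], spec$scr[2], spec$scr[3])
    alb <- rlnorm_trunc(n, spec$alb[1], spec$alb[2], spec$alb[3])
    sex <- ifelse(runif(n) < spec$male_fraction, "male", "female")
    weight <- rlnorm_trunc(n, spec$weight[1], spec$weight[2], spec$weight[3])
    height <- rlnorm_trunc(n, spec$height[1], spec$height[2], spec$height[3])
    for (i in seq_len(max_attempts)) {
      bad <- bmi(weight, height) >= spec$bmi_max
      if (!any(bad)) break
      nb <- sum(bad)
      weight[bad] <- rlnorm_trunc(nb, spec$weight[1], spec$weight[2],
                                  spec$weight[3])
      height[bad] <- rlnorm_trunc(nb, spec$height[1], spec$height[2],
                                  spec$height[3])
    }
    if (any(bmi(weight, height) >= spec$bmi_max)) {
      stop("could not satisfy the BMI constraint within `max_attempts`")
    }
    derive_covariates(data.frame(id = seq_len(n), age = age, sex = sex,
                                 weight = weight, height = height,
                                 scr = scr, alb = alb,
                                 stringsAsFactors = FALSE))
  })
}

#' Assign maintenance regimens to a cohort
#'
#' Daily doses are sampled from the spec's dose levels; daily doses of
#' 1000 mg or more are split into two administrations per day (every
#' 12 h), smaller doses are given once daily.
#'
#' @param cohort covariate data.frame from [generate_covariates()].
#' @param spec a [cohort_spec()] providing dose levels, probabilities,
#'   days of therapy and infusion duration.
#' @param seed overrides `spec$seed`.
#' @return data.frame with one row per subject: `id`, `daily_dose`,
#'   `dose_per_admin`, `interval`, `n_doses`, `infusion_duration`.
#' @export
generate_regimens <- function(cohort, spec = cohort_spec(),
                              seed = spec$seed) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  with_seed(derive_seed(seed, "regimens"), {
    daily <- spec$dose_levels[sample.int(length(spec$dose_levels), n,
                                         replace = TRUE,
                                         prob = spec$dose_probs)]
    split <- daily >= 1000
    data.frame(id = cohort$id,
               daily_dose = daily,
               dose_per_admin = ifelse(split, daily / 2, daily),
               interval = ifelse(split, 12, 24),
               n_doses = ifelse(split, 2 * spec$days, spec$days),
               infusion_duration = spec$infusion_duration)
  })
}

regimen_from_row <- function(row) {
  regimen(dose = row$dose_per_admin, interval = row$interval,
          infusion_duration = row$infusion_duration, n_doses = row$n_doses)
}

#' Simulate noisy concentration observations
#'
#' Each subject receives 2-4 samples. Troughs are drawn immediately before
#' a late dose (or 1 interval after the final dose); peaks are drawn
#' `peak_delay` hours after the end of a late infusion. True
#' concentrations come from the analytic two-compartment model at
#' individual parameters generated under `truth`; observations add the
#' residual error of `truth$sigma`. Negative draws under additive error
#' are resampled (or truncated at zero). Observations below the limit of
#' quantitation are flagged `BLQ = 1` (and excluded from fitting
#' downstream).
#'
#' @param cohort covariate data.frame.
#' @param regimens regimen data.frame from [generate_regimens()].
#' @param truth generating [vcm_model()] (structural values, random
#'   effect, residual error).
#' @param spec a [cohort_spec()] (sampling configuration).
#' @param seed overrides `spec$seed`.
#' @param negative `"resample"` or `"truncate"` policy for negative
#'   concentration draws.
#' @return a [pk_dataset] (NONMEM-style event data.frame).
#' @export
generate_observations <- function(cohort, regimens,
                                  truth = vcm_final_model(),
                                  spec = cohort_spec(), seed = spec$seed,
                                  negative = c("resample", "truncate")) {
  stopifnot(is.data.frame(cohort), is.data.frame(regimens),
            inherits(truth, "vcm_model"))
  negative <- match.arg(negative)
  n_counts <- as.integer(names(spec$samples_per_subject))
  with_seed(derive_seed(seed, "observations"), {
    rows <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      cov <- cohort[i, ]
      reg_row <- regimens[regimens$id == cov$id, ]
      reg <- regimen_from_row(reg_row)
      sched <- dose_schedule(reg)
      eta <- sample_eta(truth, 1)
      p <- individual_params(cov, eta = eta, model = truth)

      n_samp <- n_counts[sample.int(length(n_counts), 1,
                                    prob = spec$samples_per_subject)]
      is_peak <- runif(n_samp) < spec$peak_fraction
      nd <- reg$n_doses
      late <- seq.int(max(2, nd - 3), nd)  # steady-state-ish window
      trough_cand <- c(sched$time[late[-1]], sched$time[nd] + reg$interval)
      peak_cand <- sched$time[late] + reg$infusion_duration + spec$peak_delay

      n_tr <- sum(!is_peak)
      n_pk <- sum(is_peak)
      jit <- spec$time_jitter
      tt_tr <- sample_times(trough_cand, n_tr) - runif(n_tr, 0, jit)
      tt_pk <- sample_times(peak_cand, n_pk) +
        runif(n_pk, -min(jit, spec$peak_delay - 0.1), jit)
      tt <- c(tt_tr, tt_pk)
      type <- rep(c("trough", "peak"), c(sum(!is_peak), sum(is_peak)))
      ord <- order(tt)
      tt <- tt[ord]; type <- type[ord]

      f <- concentration(p, sched, tt)
      sdv <- sqrt(truth$sigma$add^2 + (truth$sigma$prop * f)^2)
      dv <- f + sdv * rnorm(length(f))
      if (negative == "resample") {
        for (k in 1:100) {
          neg <- dv < 0
          if (!any(neg)) break
          dv[neg] <- f[neg] + sdv[neg] * rnorm(sum(neg))
        }
      }
      dv <- pmax(dv, 0)

      dose_rows <- data.frame(
        ID = cov$id, TIME = sched$time, EVID = 1, AMT = sched$amt,
        RATE = ifelse(sched$dur > 0, sched$amt / sched$dur, 0),
        DV = NA_real_, MDV = 1, TYPE = "", BLQ = 0)
      obs_rows <- data.frame(
        ID = cov$id, TIME = tt, EVID = 0, AMT = 0, RATE = 0,
        DV = dv, MDV = 0, TYPE = type,
        BLQ = as.integer(spec$lloq > 0 & dv < spec$lloq))
      blk <- rbind(dose_rows, obs_rows)
      blk$AGE <- cov$age; blk$SEX <- sex_indicator(cov$sex) == 0
      blk$SEX <- as.integer(blk$SEX)  # 1 = male, 0 = female
      blk$WT <- cov$weight; blk$HT <- cov$height
      blk$SCR <- cov$scr; blk$ALB <- cov$alb
      rows[[i]] <- blk
    }
    as_pk_dataset(do.call(rbind, rows))
  })
}

# Sample k distinct times from candidates (with replacement only if
# candidates run short, which the 2-4 sample default never triggers).
sample_times <- function(cand, k) {
  if (k == 0) return(double())
  cand[sample.int(length(cand), k, replace = k > length(cand))]
}

#' One-stop cohort simulation
#'
#' Runs [generate_covariates()], [generate_regimens()] and
#' [generate_observations()] under per-stage seeds derived from the spec's
#' master seed.
#'
#' @param spec a [cohort_spec()].
#' @param truth generating [vcm_model()].
#' @param seed master seed (overrides `spec$seed`).
#' @return list with `cohort`, `regimens`, and `data` (a [pk_dataset]).
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_subjects = 5, seed = 1))
#' head(sim$data)
#' @export
simulate_cohort <- function(spec = cohort_spec(), truth = vcm_final_model(),
                            seed = spec$seed) {
  cohort <- generate_covariates(spec, seed = seed)
  regimens <- generate_regimens(cohort, spec, seed = seed)
  data <- generate_observations(cohort, regimens, truth, spec, seed = seed)
  list(cohort = cohort, regimens = regimens, data = data)
}
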