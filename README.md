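# vancopk

Population pharmacokinetics and AUC-guided dosing of vancomycin in
adults of advanced age.

Vancomycin dosing is steered by the 24-hour steady-state area under the
concentration–time curve: efficacy against MRSA requires
AUCss/MIC ≥ 400, while AUCss > 600 µg·h/mL raises the risk of acute
kidney injury. Clearance (CL) is conventionally predicted from
Cockcroft–Gault creatinine clearance (CLcr), but in patients aged 75
years and older — with reduced muscle mass and frequent
hypoalbuminemia — CLcr alone misestimates CL, especially when serum
creatinine is low (< 0.6 mg/dL). `vancopk` implements, end to end, a
population model for this population in which serum albumin joins CLcr
as a clearance covariate:

```
CL (L/h) = 1.96 · (CLcr / 3.09)^0.63 · (Alb / 2.3)^0.22 · exp(ηCL)
Q = 4.86 L/h,  Vc = 31.78 L,  Vp = 53.64 L
```

with a two-compartment intravenous-infusion disposition model
(intercompartmental clearance Q, central and peripheral volumes Vc and
Vp), ηCL ~ N(0, ω²), and CLcr in L/h (3.09 L/h ≡ 51.5 mL/min).

The package is for pharmacometricians and clinical-pharmacology
researchers who want to refit, validate, or exercise this model class
without access to patient-level data. It provides:

* **Analytic PK core** — closed-form two-compartment multiple-infusion
  concentrations, steady-state peak/trough, and AUCss = daily dose / CL.
* **Covariate engine** — BMI, Cockcroft–Gault, the Japanese eGFR
  equation, and a configurable covariate-model registry (YAML in/out).
* **FOCE-I population estimation** (`fit_population()`) with stepwise
  covariate selection (ΔOFV > 3.85), nonparametric bootstrap,
  empirical-Bayes estimates, η-shrinkage, conditional weighted
  residuals, and visual predictive checks. The likelihood kernel is
  compiled (Rcpp).
* **MAP Bayesian individual estimation** (`map_fit()`) of CL from
  sparse peak/trough samples, plus AUC-500 dose targeting on the 250-mg
  grid.
* **Model validation** — MAE/MSE of CL and of the AUC-500 dose against
  reference clearances, with the age ≥ 75 and SCr < 0.6 mg/dL
  subgroups.
* **Monte-Carlo dosing engine** — probability of target attainment
  (AUCss/MIC ≥ 400) against the Japanese MRSA surveillance MIC
  distribution, AUCss > 600 toxicity-risk classes, optimal-dose search
  over the nine clinical daily doses, and the CLcr × albumin dosing
  nomogram — each backed by a closed-form normal-quantile oracle.
* **Synthetic cohort generator** emulating the modeled population
  (n = 159, age 84 (75–99) years, weight 47 (26–70) kg, SCr 0.64
  (0.22–3.00) mg/dL, Alb 2.3 (1.2–4.2) g/dL, 57.9% male, BMI < 25,
  ~417 peak/trough samples), so every stage is testable.

## Worked example

```r
library(vancopk)

## The shipped covariate model
vcm_final_model()
#> <vcm_model> final-elderly
#>   CL (L/h) = 1.96 * (clcr/3.09)^0.63 * (alb/2.3)^0.22 * exp(etaCL)
#>   Q  (L/h) = 4.86
#>   Vc (L)   = 31.78
#>   Vp (L)   = 53.64
#>   omega_cl = 0.11 (sd); sigma: combined (add 0.3 mg/L, prop 0.1)

## Albumin matters: at CLcr 5.1 L/h (85 mL/min), dropping Alb from 3.5
## to 1.5 g/dL lowers clearance from 3.29 to 2.73 L/h
predict_clearance(5.1, 1.5, eta = 0.11)   # 2.730762
predict_clearance(5.1, 3.5, eta = 0.11)   # 3.290324

## Steady-state exposure for a typical frail patient on 500 mg q12h
p <- individual_params(list(clcr = 2.4, alb = 2.5))
steady_state_peak_trough(p, regimen_for_daily_dose(1000))
#> $peak   33.41638     $trough  19.6138

## Probability of target attainment at one nomogram cell
simulate_pta(750, clcr = 2.4, alb = 1.5, seed = 1)
#> PTA at 750 mg/day: 0.887 (MC se 0.0026); P(AUCss>600) 0.036 [mild risk]
```

The PTA of 0.887 means that 88.7% of 15,000 simulated patients with
CLcr 40 mL/min and albumin 1.5 g/dL attain AUCss/MIC ≥ 400 on
750 mg/day — the smallest of the nine daily doses to clear the 85%
efficacy threshold — while only 3.6% exceed the AUCss 600 toxicity
mark (mild risk). The full nomogram:

```r
build_nomogram(n_sim = 15000, seed = 1)
#> Optimal daily vancomycin dose (mg/day), PTA >= 85% for AUCss/MIC >= 400
#>         CLcr 1.2 CLcr 1.5 CLcr 1.8 CLcr 2.1 CLcr 2.4 CLcr 2.7 CLcr 3 ...
#> Alb 1.5 500      750      750      750      750      1000     1000
#> Alb 2   500      750      750      750      1000     1000     1000
#> Alb 2.5 750      750      750      750      1000     1000     1000
#> Alb 3   750      750      750      1000     1000     1000     1000
#> Alb 3.5 750      750      750      1000     1000     1000     1000
```

A full simulate–fit cycle on a virtual cohort:

```r
sim <- simulate_cohort(cohort_spec(n_subjects = 60, seed = 1))
fit_population(sim$data, init = vcm_final_model())
#> FOCE-I population fit: 60 subjects, 156 observations
#>   OFV (-2LL) 685.61 | AIC 703.61 | 9 parameters | converged
#>       param estimate      se cv_pct      ci_lo   ci_hi
#>          cl  1.95700 0.07980   4.07  1.8070000  2.1200
#>          vc 27.29000 3.59000  13.20 21.0900000 35.3200
#>     cl_clcr  0.68950 0.06030   8.74  0.5713000  0.8076
#>     ...
#>   eta-shrinkage: 16.6%
```

The typical clearance (1.96 L/h) and the CLcr exponent (0.63) used to
generate the cohort are recovered within their standard errors.

## Further reading

The methods vignette (`vignettes/vancomycin-poppk.Rmd`) documents the
model and estimation approximations, the synthetic-data design and what
it does and does not emulate, numerical choices, and limitations.
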