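---
title: "Methods: population PK and AUC-guided dosing of vancomycin in advanced age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK and AUC-guided dosing of vancomycin in advanced age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancopk)
```

`vancopk` implements a complete population-pharmacokinetic workflow for
vancomycin in patients aged 75 years and older: structural model,
FOCE-I estimation and diagnostics, MAP Bayesian individualization,
predictive-performance validation, and Monte-Carlo dose optimization.
This vignette is the package's account of the underlying science — the
models, the approximations, the synthetic-data design, and the
numerical and design choices a maintainer would want explained.

## The structural and statistical model

Disposition follows a two-compartment model with zero-order
intravenous infusion and first-order elimination, parameterized by
clearance CL, intercompartmental clearance Q, and central/peripheral
volumes Vc, Vp. The central concentration after a dose is the familiar
bi-exponential

$$C(t) = A_\alpha e^{-\alpha t} + A_\beta e^{-\beta t},$$

where $\alpha\beta = k_{10}k_{21}$ and
$\alpha + \beta = k_{10} + k_{12} + k_{21}$ with micro-constants
$k_{10} = CL/V_c$, $k_{12} = Q/V_c$, $k_{21} = Q/V_p$. Multiple-dose
profiles are exact superpositions of per-dose infusion solutions
(`concentration()`); steady state uses the geometric accumulation
$e^{-\lambda\tau}/(1 - e^{-\lambda\tau})$ per exponential rather than
simulating many doses (`steady_state_concentration()`).

Between-subject variability enters clearance log-normally,

$$CL_i = \theta_1
  \left(\frac{CLcr_i}{3.09}\right)^{\theta_2}
  \left(\frac{Alb_i}{2.3}\right)^{\theta_3} e^{\eta_i},
  \qquad \eta_i \sim N(0, \omega^2),$$

with CLcr the Cockcroft–Gault estimate in L/h and Alb serum albumin in
g/dL. The shipped defaults are the fitted values for the elderly
population: $\theta_1 = 1.96$ L/h, $\theta_2 = 0.63$,
$\theta_3 = 0.22$, Q = 4.86 L/h, Vc = 31.78 L, Vp = 53.64 L
(`vcm_final_model()`). Q, Vc and Vp carry no random effects. Residual
error supports additive, proportional and combined families
(`res_error()`), with variance
$\sigma_{add}^2 + \sigma_{prop}^2 f^2$ at prediction $f$.

**The 0.11 dispersion.** The published dispersion of $\eta_{CL}$ is a
single number, 0.11, whose reading (standard deviation vs variance) is
ambiguous in the source material; the worked clearance examples apply
it directly as `exp(0.11)`. The package supports all three readings
through `omega_type` (`"sd"`, `"variance"`, `"fixed_offset"`) and
defaults to **SD**: the closed-form dose-attainment oracle (below)
reproduces the published optimal doses at CLcr 2.4 L/h (750 mg at
albumin 1.5 g/dL, 1000 mg at 2.0–3.5 g/dL) under the SD reading but
not under the variance reading, which more than doubles the spread of
simulated clearances.

**Units and conventions.** Time is in hours from the first dose;
concentrations in mg/L (≡ µg/mL); CLcr converts as
1 mL/min = 0.06 L/h. AUCss is the 24-hour steady-state area,
`daily_dose / CL` for this linear drug — the twice-daily split of
doses ≥ 1000 mg changes the concentration profile but not AUCss.

**Degenerate inputs.** When $\alpha \approx \beta$ the partial-fraction
coefficients suffer catastrophic cancellation; the implementation
clamps the relative root gap at $10^{-9}$, which agrees with the
repeated-root series limit to within that tolerance. $Q = 0$ collapses
cleanly to the one-compartment solution and is flagged degenerate by
`disposition_constants()`. `(1-e^{-\lambda t})/\lambda` is evaluated
via `expm1` so $\lambda \to 0$ infusion terms stay accurate.

## FOCE-I estimation

`fit_population()` minimizes the first-order-conditional-estimation
(with interaction) approximation to $-2\log$ marginal likelihood. Per
subject, the inner objective

$$h(\eta) = \sum_j \left[\log v_j(\eta) +
  \frac{(y_j - f_j(\eta))^2}{v_j(\eta)}\right] + \frac{\eta^2}{\omega^2}$$

is minimized over the scalar $\eta$ by Brent search on $[-7, 7]$ (inner
tolerance $10^{-10}$), with the residual variance $v_j$ evaluated at
the conditional prediction (the "interaction"). The model is then
linearized at the mode $\hat\eta$ with sensitivity
$G_j = \partial f_j/\partial\eta|_{\hat\eta}$ (central differences,
step $10^{-4}$), giving the marginal contribution

$$-2\ell_i = \log|\Sigma_i| + r_i^\top \Sigma_i^{-1} r_i + n_i\log 2\pi,
\qquad \Sigma_i = G_i\,\omega^2 G_i^\top + V_i, \quad
r_i = y_i - f_i(\hat\eta) + G_i\hat\eta,$$

evaluated in $O(n_i)$ via the matrix-determinant lemma and Woodbury
identity. Setting $\omega = 0$ reduces the objective exactly to the
extended-least-squares fixed-effects deviance; the test suite verifies
the full objective against adaptive-quadrature integration of the
marginal likelihood on sparse subjects (agreement well within 0.5
units, typically < 0.1).

The outer problem runs a bounded quasi-Newton (`nlminb`) on a
log-transformed scale for positive parameters (structural values,
$\omega$ as SD, $\sigma$ components) and the identity scale for
covariate exponents. Standard errors come from the inverse Hessian of
the objective at the optimum (`optimHess`; variance $= 2H^{-1}$ for a
$-2\log L$ objective), delta-method transformed back; AIC = OFV + 2k.
Because the inner search leaves $\sim 10^{-9}$ noise on the objective,
`nlminb` occasionally reports "false convergence" at a genuine optimum;
convergence is therefore assessed by restarting at the solution and
requiring less than $10^{-3}$ further improvement.

Internally $\omega$ is estimated as an SD on the log scale and
reported as such; fitted models always carry `omega_type = "sd"`.

**Diagnostics.** Empirical Bayes estimates are the conditional modes;
shrinkage is $100(1 - SD(\hat\eta)/\omega)$. CWRES decorrelates the
linearized population residual by the Cholesky factor of $\Sigma_i$ and
should be approximately standard normal (±3) under a correct model —
the suite shows a one-compartment misfit of two-compartment data is
flagged both by ΔOFV and by biased peak residuals. The VPC simulates
replicate datasets at the observed design and compares observed
percentiles (5th/50th/95th by default) with their simulation envelopes
in time-after-dose bins (equal-count binning; empty bins dropped with
a notice).

**Covariate selection.** `stepwise_select()` performs forward
inclusion / backward elimination with the ΔOFV > 3.85 criterion
(P < 0.05 for one parameter; the backward threshold defaults to the
same value since only one is stated). Continuous candidates enter as
power terms normalized to their cohort median; sex as a multiplicative
factor. Clearance accuracy at steady state is the clinically decisive
quantity here, so when the best clearance and best volume candidates
are within 3.85 of each other the clearance term wins.

**Bootstrap.** `pk_bootstrap()` resamples subjects with replacement,
refits warm-started from the point estimates, and summarizes replicate
medians with percentile intervals; non-converged replicates are
excluded and counted, warning above 20%.

## MAP Bayesian individualization and validation

`map_fit()` maximizes the posterior of $\eta$ (residual likelihood ×
normal prior) for one subject's sparse observations — the computation
TDM software performs when it reports a "Bayesian" clearance from peak
and trough samples. A flat-prior mode reproduces unpenalized least
squares; with no observations the prior mode (population prediction)
is returned and flagged. Dose individualization maps clearance to the
daily dose achieving AUCss 500 µg·h/mL, rounded to the nearest 250-mg
multiple with ties up (`dose_for_target_auc()`); the reference workflow
this emulates reports doses on the same grid, and both predicted and
reference doses are rounded before comparison.

Because the software prior actually used for the published reference
clearances is not available as printed parameters, the validation
harness injects the generating model as the MAP prior — a synthetic
surrogate that preserves the estimator's structure. `compare_models()`
then scores each candidate model's population-predicted clearance (and
its AUC-500 dose) against the per-subject references by MAE and MSE
with normal-approximation 95% intervals, in the two reported
subgroups: all subjects aged ≥ 75, and those with SCr < 0.6 mg/dL.
The published external-validation magnitudes (e.g. MAE ≈ 0.6 L/h)
belong to an eight-hospital dataset that was never deposited, so the
package's claims are the simulation-based ones: zero error under
self-comparison, Jensen's inequality MSE ≥ MAE² in every cell, and
superiority of the generating covariate model over an albumin-free
comparator across replicate cohorts.

## Monte-Carlo dose optimization

`simulate_pta()` draws, per virtual patient, $\eta$ and a MIC from the
Japanese MRSA surveillance distribution
{0.25: 0.1%, 0.5: 11.6%, 1.0: 79.3%, 2.0: 9.0%} and computes
AUCss = daily dose / CL. PTA is the fraction attaining
AUCss/MIC ≥ 400 (boundary inclusive, with a strict-comparison switch);
the probability of AUCss > 600 is classified mild (< 10%), moderate
(10–25%), or severe (> 25%). With 15,000 patients per dose the
Monte-Carlo standard error of a PTA near 0.85 is ≈ 0.003, and it is
reported with every result so near-threshold cells are auditable.

Everything has a closed-form check: under the log-normal clearance
model,

$$PTA = \sum_m p_m\,
  \Phi\!\left(\frac{\log\left(\mathrm{dose}/(400\, m\, CL_{typ})\right)}
  {\omega}\right),$$

and similarly $P(AUC > 600)$ (`pta_oracle()`). The suite requires the
engine to match the oracle within 3 Monte-Carlo standard errors on a
grid of cells.

`optimal_dose()` searches the nine clinical daily doses {250, …, 3000}
ascending for the first with PTA ≥ 85%. One set of $(\eta,
\mathrm{MIC})$ draws is shared across all doses of a search and all
cells of a nomogram (common random numbers): PTA is then *exactly*
monotone in dose and in the typical clearance, removing Monte-Carlo
flicker from the dose tables without biasing any single estimate.
`build_nomogram()` tabulates the optimal dose over albumin 1.5–3.5
g/dL × CLcr 1.2–5.1 L/h (20–85 mL/min) with each cell's PTA, toxicity
probability and risk class; cells where no dose attains the threshold
render "none". `dose_range_over_cl_grid()` treats each value of a
clearance grid (default 0.5–3.75 L/h, the range spanned by the study
population) as the typical clearance and reports the extremes of the
minimal attaining dose — 250 and 2000 mg under the defaults — in
either the stochastic mode or a deterministic strict-boundary mode
(success iff dose/CL/MIC > 400 exactly), which brackets the η-reading
ambiguity. At a handful of printed low-clearance cells (e.g. albumin
2.0 g/dL, CLcr 1.2 L/h) the closed-form oracle disagrees with the
published table under every single-parameter η reading (500 mg already
attains PTA ≈ 0.87 ≥ 0.85); those cells presumably involved covariate
resampling not derivable from the text, and the package reports its
oracle-consistent values.

## The synthetic cohort: what it emulates, and what not

No patient data were deposited, so `cohort_spec()` /
`simulate_cohort()` generate virtual cohorts with the modeled
population's published margins: n = 159; age 84 (75–99) years; weight
47 (26–70) kg; height 158 (135–180) cm; SCr 0.64 (0.22–3.00) mg/dL;
albumin 2.3 (1.2–4.2) g/dL; 57.9% male; BMI < 25 kg/m² (median ≈ 18.6
emerges from the weight/height margins); daily doses 250–3000 mg with
band frequencies matching the reported dose distribution (27.7% below
1000 mg, 67.9% at 1000–2000 mg, median 1500 mg); and ≈ 417
concentration samples at a 65:352 peak:trough ratio from 2–4 samples
per subject. Since only medians and ranges are published, continuous
covariates use log-normal distributions with the median as the
log-mean, truncated to the observed range by inverse-CDF sampling —
the simplest family honoring both statistics; weight and height are
jointly resampled until BMI < 25, with an up-front feasibility check.
The derived CLcr median then lands near the reported 3.06 L/h without
being forced.

Dosing and sampling conventions not stated in the source are fixed
once as realistic defaults: 1-hour infusions; five days of therapy
with samples drawn in the final dosing intervals (near steady state);
troughs immediately before a dose; peaks nominally 1 hour after the
end of infusion; daily doses ≥ 1000 mg split twice daily. Observation
times carry a ±0.75-hour uniform jitter around those nominal times
(`time_jitter`). The jitter matters: with every peak drawn at exactly
the same time after dose, the three distribution parameters (Q, Vc,
Vp) lie on a likelihood ridge and the recovered Vc wandered between
13 and 31 L across realizations; with the draw-time variability that
real therapeutic monitoring always has, Vc is recovered within about
10% at study scale. Residual error is generated as combined (additive
0.3 mg/L, proportional 10%, consistent with the reported assay
reproducibility of "below 15%"). Observations below the 2.5 mg/L
quantitation limit are flagged and excluded from fitting, mirroring
the analysis dataset's exclusion rule; negative additive-noise draws
are resampled by default (truncation at zero is available).

What the generator does **not** emulate: within-subject renal-function
drift (covariates are baseline constants, as in the model), assay
batch effects, correlated covariates beyond the BMI constraint (e.g.
the weak observed albumin–CLcr correlation of −0.12), adherence gaps,
and any non-log-normal covariate shapes. Passing recovery tests
therefore demonstrate correctness of the estimator under the model's
own assumptions — an inverse-crime design — not robustness to real
data pathologies.

## Problem sizes and numerical settings

The test suite and the acceptance script run at the sizes the analysis
itself uses where that is cheap (15,000 Monte-Carlo patients per dose;
159-subject recovery fits with ~417 observations) and at reduced but
statistically adequate sizes where full scale adds nothing but time
(40-subject cohorts for the bootstrap-consistency and bias checks, 200
of 1000 bootstrap replicates, 10–20 replicate cohorts for operating
characteristics). Optimizer bounds are generous (e.g. clearance
0.02–100 L/h on the log scale); exponents live in [−5, 5]; residual
variances are floored at $10^{-12}$ to keep degenerate noise-free
fits finite. Collinear covariate candidates are both offered in
selection, with ties broken by larger ΔOFV then registry order.

## Known limitations

* One random effect (on CL) — matching the final model — so no
  omega-block covariances are estimated even though the interface
  could be extended to them.
* FOCE-I is an approximation; its documented accuracy here is the
  quadrature comparison on sparse designs, not an exact-likelihood
  guarantee.
* BLQ observations are excluded rather than integrated (no censored
  likelihood); fine at a 2.5 mg/L limit with trough-dominated
  sampling, but a likelihood-based BLQ treatment would be preferable
  for less sensitive assays.
* The MAP reference in the validation harness is a synthetic surrogate
  for the clinical software's prior, whose parameters are not public;
  conclusions about relative model accuracy transfer only to the
  extent that surrogate is adequate.
* No interoccasion variability, lag times, or nonlinear elimination.
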