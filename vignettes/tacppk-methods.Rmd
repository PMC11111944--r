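---
title: "Population PK and PK-informed machine learning for tacrolimus troughs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tacppk methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tacppk` predicts tacrolimus trough concentrations (C₀) in renal-transplant
recipients in two coupled stages: a nonlinear mixed-effects population
pharmacokinetic (PPK) model, and a machine-learning regressor whose key
feature is the PPK model's individual forecast. This vignette is the
package's account of the science: the models, their assumptions, the
tunable parameters, what the synthetic cohorts do and do not emulate, and
the numerical decisions underneath.

## The population model

Trough-only TDM data support a one-compartment model with first-order
absorption and elimination. The absorption rate constant is fixed at
`ka = 3.86` h⁻¹ — troughs carry essentially no absorption-phase
information, so `ka` is never estimated. (Different sources print 3.84 and
3.86 for this constant; the package uses 3.86, the value reported
consistently in tabulated parameter sets.) Bioavailability F is absorbed
into the apparent parameters V/F and CL/F, which is the only identifiable
parameterisation for oral trough data.

Between-patient variability is log-normal on both dispositional
parameters, and the residual is additive on the log scale:

$$V/F_i = \theta_V e^{\eta_{V,i}}, \qquad
  CL/F_{ij} = \theta_{CL}\,\prod_k e^{\beta_k x_{kij}}\, e^{\eta_{CL,i}},
  \qquad \ln C_{obs,ij} = \ln C_{pred,ij} + \varepsilon_{ij}$$

with $\eta \sim N(0,\Omega)$, $\Omega$ diagonal, and
$\varepsilon \sim N(0,\sigma^2)$. Because the residual is homoscedastic in
the transformed space, the log-scale SD $\sigma$ times 100 is comparable
to a CV%; the shipped final preset uses $\sigma = 0.356$ (reported as
35.6%). Ω is diagonal — tabulated estimates report no η covariance — and
inter-individual variability is reported as CV% = 100·√ω².

Covariates act multiplicatively on CL/F in exponential-linear form,
uncentred, so the printed final equation's algebra is preserved exactly:

$$CL/F = 70.6 \times e^{-0.348\,\mathrm{CYP3A5}} \times e^{-0.122\,\mathrm{HCT}}$$

with CYP3A5 the *3 allele count (0, 1, 2) and HCT a fraction. Uncentred
HCT means θ_CL = 70.6 L/h is the extrapolated clearance of a hypothetical
HCT = 0 patient; all recovery checks use this same convention, so the
convention cancels. The genotype ratios e^{−0.348} = 70.6% and
e^{−0.696} = 49.9% (heterozygous and non-expresser clearance relative to
*1/*1) are pure functions of the coefficient and are the package's most
exactly checkable quantities.

Covariates may vary between TDM occasions (HCT rises with recovery). The
prediction engine treats the elimination rate as piecewise constant:
advancing from one event record to the next uses the covariates attached
to the record being advanced to, with dose records carrying the last
observation's panel forward (and the first panel backward before the first
trough). Within an inter-occasion interval a regular BID dose train is
advanced in closed form by geometric accumulation, so a year of dosing
costs the same as one interval; the compressed path agrees with dose-by-
dose propagation to machine precision and is unit-tested against both an
ODE integrator and the steady-state accumulation formula. When
$|k_a - k_e|$ falls below a relative 10⁻⁸ the limiting form
$A\,k_a\,\Delta t\,e^{-k_a \Delta t}$ replaces the ill-conditioned
quotient.

## Estimation

`ppk_fit()` maximises the FOCE-approximate marginal likelihood: per
subject, the joint density of log-observations and η is Laplace-
approximated at the conditional mode η̂, with the model linearised to
first order in η about η̂ (no interaction term is needed because the
residual is additive and homoscedastic on the log scale). The subject's
contribution is

$$-2\ell_i = \sum_j r_{ij}^2/\sigma^2 + n_i\ln(2\pi\sigma^2) +
  \hat\eta^T\Omega^{-1}\hat\eta + \ln\det\!\big(I + (G^TG/\sigma^2)\,\Omega\big)$$

written so that ω² → 0 degenerates smoothly to the fixed-effects
likelihood. The inner mode search is a damped Gauss–Newton iteration with
analytic gradients (the sensitivity of the central amount to the
log-elimination perturbation is propagated alongside the state), gradient
tolerance 10⁻⁷, restarted from η = 0 on every outer evaluation so the
objective is a pure function of the parameters. The quadrature error of
this approximation is checked against adaptive Gauss–Hermite integration
(21 nodes per dimension) in the test suite.

The outer problem optimises (log θ_V, log θ_CL, β's, log ω², log σ²) with
covariate coefficients scaled by their covariate's SD. Because the inner
mode search can hop between basins as the outer parameters move, the
outer surface carries small kinks; a Nelder–Mead pass (relative tolerance
10⁻⁹) followed by a quasi-Newton polish (`nlminb`, relative OFV tolerance
10⁻⁷) proved far more reliable than gradient-based optimisation alone.
Variance parameters are bounded inside [10⁻⁸, 25] so degenerate
(noise-free) data remain identifiable; `fix =` lets callers pin any
parameter, which is how the noiseless-recovery test isolates the typical
values. Standard errors come from a central-difference Hessian on the
scaled coordinates (step 5·10⁻³) mapped back by the delta method;
RSE% = 100·SE/|estimate|, with ω reported as CV% carrying half the RSE of
ω². A non-positive curvature direction reports `NA` rather than a number.

MAP (empirical-Bayes) estimation reuses the inner problem with the
population parameters fixed; a record with no usable troughs returns the
prior mode, flagged. MAP shrinkage toward zero relative to the
unpenalised per-subject fit is asserted property-style.

## Covariate selection

Forward inclusion adds, one per step with a refit between steps, the
candidate with the largest OFV drop ≥ 6.63 (χ², p < 0.01, df 1); backward
elimination then removes, while possible, the retained covariate whose
removal raises the OFV by the least amount < 7.88 (p < 0.005). Both
boundaries are inclusive for the stricter decision (a drop of exactly
6.63 includes; a rise of exactly 7.88 retains). Ties break by larger OFV
change, then lexicographic covariate name, making the search invariant to
candidate ordering. Only CL/F effects are searched: trough-only data
barely identify V/F, so volume covariates are deliberately unsupported.
Candidates whose refit does not converge are skipped with a warning, never
a crash. The default candidate panel is CYP3A5, HCT, WT, POD, RBC, DBIL,
BUN, CLcr, ALB, sex and the three co-medication flags.

## Diagnostics

CWRES follow the FOCE linearisation: the log-residual vector recentred by
$G\hat\eta$ and whitened by the Cholesky factor of
$G\Omega G^T + \sigma^2 I$. Under the generating model they are standard
normal to good approximation (the suite checks mean within ±0.1 and
variance in [0.8, 1.2] on ~900 observations).

The VPC simulates replicate datasets (default 1000; fewer than 100 warns)
under the observed design — same doses, times and covariates, fresh η per
subject and ε per observation — and compares observed 5th/50th/95th
percentiles per postoperative-day bin (deciles by default; no binning
rule is tabulated in the source material, so it is configurable) with
each percentile's 95% band across replicates. One caveat discovered
during development and worth stating: cohorts generated with trough-
guided titration are *feedback-adapted* — each patient's realised doses
already compensate their own η — so resimulating fresh η under the fixed
realised design inflates the simulated spread relative to the observed
one and the observed points sit inside the band slightly too often
(≈95%). The calibration check therefore resimulates the observations once
under the fixed design before running the VPC, which restores the nominal
≈90% coverage. Real TDM data carry the same adaptation; plain VPCs on
titrated cohorts should be read with that in mind.

Error metrics are the standard set — MAE, MAPE (%), RMSE, R² — plus the
signed mean percentage error MPE (with a normal-approximation 95% CI) and
MRSE%, defined here as the root-mean-squared relative error × 100, the
reading that makes it commensurate with MAPE-scale errors. Relative
metrics refuse zero observations; a constant observed vector reports
R² = 0 with a warning.

## The machine-learning stage

Each non-censored trough becomes one feature row: WT, AMT (daily dose in
effect at the trough, mg — "current dose" is not otherwise defined for a
BID regimen), POD, RBC, HCT, DBIL, BUN, CLcr, ALB, CYP3A5, three
co-medication flags, UDOSE (cumulative mg/kg administered in
[previous trough, current trough); the first row accumulates from the
first dose) and IPRE, the covariate-free (basic) PPK model's individual
prediction. IPRE is a one-step-ahead forecast: the patient's η is
estimated by MAP from strictly earlier troughs only (prior mode for the
first), so the feature never sees the value it predicts. The same-time
post-hoc variant exists behind `forecast = FALSE` for comparison; it is
leaky for prospective use, and the tests verify it tracks the target more
closely than the honest forecast. The pipeline's comparison table uses
one-step-ahead MAP predictions for the PPK rows as well, so the PPK and
ML stages are compared like for like.

Three regressor families are supported by contract: gradient-boosted
trees (xgboost), ε-SVR with an RBF kernel (e1071) and a single-hidden-
layer feed-forward network (nnet; the family is "plain fully connected
regressor" — depth beyond one hidden layer adds nothing at a few hundred
rows). Hyperparameters are searched by a Tree-structured Parzen
Estimator written for this package: after a random start-up, observed
trials split at the best quartile; per-parameter Parzen densities (log
scale for log-uniform ranges, smoothed counts for categoricals) model the
good and bad sets, 24 candidates drawn from the good density are ranked
by density ratio. The objective is the sum of the mean inner-fold MAE
(ng/mL) and mean inner-fold MAPE (%) — a unit-mixing convention preserved
deliberately because it is how the tuning objective is defined in the
source methodology. Default search spaces bracket the usual optima for
these families (tree depth 3–10, learning rate 0.01–0.3, 50–400 rounds;
SVR C 0.1–100, γ 10⁻³–1; 4–64 hidden units, weight decay 10⁻⁵–10⁻¹).

Both cross-validation layers group folds by patient — rows within a
patient are strongly correlated, and grouping is what makes the outer
metrics honest. The nested scheme re-tunes inside every outer fold;
reported hyperparameters come from a final tune on all rows. Everything
is deterministic given the seed.

Attribution: for tree ensembles the package computes exact path-Shapley
values in double precision from the parsed trees, so attributions plus
base value reconstruct the (double-precision) ensemble prediction to
machine accuracy — the library's own float32 contributions miss the 10⁻⁶
additivity the tests demand, which is why the kernel is reimplemented and
cross-checked against the library to ~10⁻⁴. SVR and the network fall back
to a fixed-seed permutation-sampling estimator whose telescoping
construction keeps per-row additivity exact; it is flagged
`approximate`.

## The synthetic cohort

`generate_cohort()` emulates the design of an adult renal-transplant TDM
series: genotype frequencies 9.45/33.9/56.7% (whole-cohort values; the
training-subset frequencies differ trivially), weight 63.3 ± 12.9 kg,
marginal HCT 0.29 ± 0.056 decomposed into a patient baseline, a
saturating postoperative recovery trend (amplitude 0.07, time constant 90
days — consistent with anaemia resolving over the first months) and
occasion noise, the baseline variance solved so the pooled marginal
matches its target by construction. Labs (RBC, DBIL, BUN, CLcr, ALB) use
truncated-normal or moment-matched log-normal marginals; CLcr, not
tabulated in the source, is centred at 36 mL/min as implied by the
cohort's creatinine, weight and age. Co-medication flags are drawn at the
tabulated frequencies but have no PK effect by default (the final model
contains none); an optional voriconazole effect on CL/F exists to give
selection-power tests a plantable signal.

Dosing follows the protocol: 0.1 mg/kg/day BID rounded to 0.5 mg,
titrated after each trough by ×0.75 (above window) or ×1.25 (below)
toward 10–13 ng/mL in the first month and 5–9 ng/mL thereafter — the
multipliers and rounding are invented protocol details (only the windows
are stated in the source) and are configurable. Troughs are drawn on a
fixed schedule of 16 postoperative days spanning 3–365 (a schedule, not a
resampled POD distribution, so the occasion index is well defined), at
8 a.m. immediately before the morning dose; values outside 2–50 ng/mL
are kept and flagged censored. Censored troughs are excluded from
estimation and ML targets — no censoring likelihood is attempted because
none is specified in the source methodology.

What the generator does **not** emulate: between-covariate correlation
(weight–CLcr, RBC–HCT), irregular real-world sampling and dose-timing
noise, non-adherence, and the first-TDM heterogeneity of a real service.
Two knock-on consequences are documented honestly: (i) the VPC feedback
effect above; (ii) in the emulated cohort the *first* trough is the
best-predicted in absolute error — the weight-based starting dose pins it
at low, well-determined concentrations — whereas real cohorts typically
show the first TDM as the hardest. Per-occasion error analysis
(`per_occasion_errors()`) is implemented and tested mechanically, but
that clinical pattern should not be expected from these synthetic
cohorts, and passing tests here say nothing about it.

## Problem sizes and known limitations

Recovery experiments run at the study design (103 patients × 16 scheduled
troughs); the acceptance script reports medians over 21 simulate-and-refit
replicates, which keeps the Monte-Carlo error of the clearance medians
near 4% relative. Unit and property tests use 15–60-patient cohorts and
reduced fold/trial counts — sizes chosen so each check exercises the full
code path at the smallest scale where its property is stable. The CV% of
CL/F variability has per-replicate sampling error around 15% at this
design, so single-replicate checks of that quantity are the least stable;
the reported quantity is the median.

Known limitations: one compartment only (appropriate for trough-only
data; rich profiles would want two); no lag or transit absorption; η
covariance not estimable; V/F covariates unsupported; ω²_V is noticeably
underestimated at this design (troughs at a common 12-h post-dose time
carry little volume information — θ_V itself recovers well, and ω_V is
not a reported target); the sandwich variance estimator is not
implemented; and the TPE is a compact single-objective implementation,
not a general optimisation framework.
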