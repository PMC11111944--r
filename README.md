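# tacppk

Two-stage prediction of tacrolimus trough concentrations (C₀) in adult
renal-transplant recipients, for pharmacometricians and clinical-pharmacology
data scientists working with routine therapeutic drug monitoring (TDM) data.

Tacrolimus has a narrow therapeutic window and large between-patient
variability, driven chiefly by the CYP3A5 *1/*3 polymorphism (coded 0/1/2 by
*3 allele count) and haematocrit (HCT; tacrolimus is extensively bound to
erythrocytes). `tacppk` implements:

1. **A population pharmacokinetic (PPK) stage.** A one-compartment model
   with first-order absorption (ka fixed at 3.86 h⁻¹) and first-order
   elimination, apparent parameters V/F and CL/F with log-normal
   inter-individual variability and an additive residual on the
   log-concentration scale:

   P_i = TV(P) · e^{η_i},  η ~ N(0, Ω);  ln C_obs = ln C_pred + ε,  ε ~ N(0, σ²)

   with an exponential covariate submodel on clearance. The shipped final
   model is

   CL/F = 70.6 · e^{−0.348·CYP3A5} · e^{−0.122·HCT} (L/h), V/F = 2560 L.

   Estimation is FOCE: the marginal likelihood is approximated per subject
   by a Laplace expansion about the conditional mode of η. The package
   provides stepwise covariate selection by likelihood-ratio testing
   (forward ΔOFV ≥ 6.63, backward ≥ 7.88), empirical-Bayes (MAP)
   forecasting, conditional weighted residuals (CWRES), visual predictive
   checks (VPC) and the usual error metrics (MAE, MAPE, RMSE, R², MPE,
   MRSE%).

2. **A PK-informed machine-learning stage.** One feature row per trough:
   clinical covariates, the daily dose (AMT), cumulative dose per kg since
   the previous trough (UDOSE), and IPRE — the covariate-free PPK model's
   one-step-ahead individual prediction. Gradient-boosted trees, RBF
   support-vector regression and a feed-forward network are tuned by a
   Tree-structured Parzen Estimator (minimising mean-fold MAE + MAPE) under
   nested, patient-grouped 10×10 cross-validation, and explained by exact
   (tree) or sampling Shapley attribution.

3. **A synthetic-cohort generator** emulating the study design: 127
   patients, CYP3A5 frequencies 9.45/33.9/56.7 %, HCT 0.29 ± 0.056 rising
   with postoperative recovery, 0.1 mg/kg/day BID starting dose titrated to
   10–13 ng/mL (first month) then 5–9 ng/mL, 16 scheduled troughs over
   postoperative days 3–365, assay range 2–50 ng/mL. Every stage of the
   pipeline is therefore testable without patient data.

## Worked example

```r
library(tacppk)

coh <- generate_cohort(cohort_config(n_patients = 103), seed = 1)
fit <- ppk_fit(coh, init = ppk_preset("final"))
summary(fit)
#> FOCE fit: 103 patients, 1624 observations, OFV 1511.754 (converged)
#>
#>              estimate  rse_pct
#> theta_v     2570.1759   8.9990
#> theta_cl      68.5979  11.0777
#> beta_CYP3A5   -0.3226  13.4420
#> beta_HCT      -0.0351 883.2601
#> omega2_v       0.2388  33.1230
#> omega2_cl      0.0613  16.4991
#> sigma2         0.1240   3.7222
#>
#> Variability (reporting scale):
#>                 value rse_pct
#> IIV V/F (CV%)    48.9    16.6
#> IIV CL/F (CV%)   24.8     8.2
#> residual SD (%)  35.2     1.9
```

The typical V/F (2570 vs 2560 L) and CL/F (68.6 vs 70.6 L/h), the CYP3A5
coefficient (−0.32 vs −0.348), the CL/F variability (24.8 vs 23 CV%) and
the residual SD (35.2 vs 35.6 %) recover the generative values within
sampling error; the HCT coefficient is weakly identified (note its RSE),
as expected from a covariate whose cohort SD is only 0.056. This
simulate-and-refit experiment is exactly what `scripts/acceptance.R`
reports (as medians over 21 replicates). Downstream:

```r
typical_clearance(ppk_preset("final"), cyp3a5_code = 1, hct = 0.29)
#> [1] 48.1177        # L/h; *1/*3 carriers clear at 70.6% of *1/*1

v <- vpc(coh, fit, n_replicates = 1000, seed = 7)
plot(v)

basic   <- ppk_fit(coh, ppk_preset("basic"))
rows_tr <- build_feature_table(coh, basic)
tuned   <- tune_nested_cv(rows_tr, "xgb", n_trials = 100, seed = 7)
```

or run everything in order (`run_pipeline(pipeline_config())`): simulate →
split → basic fit → covariate selection → final fit → VPC → ML → a
comparison table of PPK-basic, PPK-final and ML test metrics.

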