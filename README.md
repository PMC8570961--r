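# meldjm

Dynamic survival prediction for liver-transplant waitlist candidates
with acute-on-chronic liver failure (ACLF).

The MELD-Na score that ranks candidates for a liver graft uses only the
most recent measurement, yet ACLF can progress within days: a patient
climbing from MELD-Na 14 to 24 in a week is in far more danger than a
patient stable at 28. `meldjm` implements a joint model that couples a
mixed-effects model for repeated MELD-Na measurements,

    y_ij = m_i(t_ij) + e_ij,   m_i(t) = x_i(t)'β + b_0i + b_1i t,
    b_i ~ N(0, D),  e_ij ~ N(0, σ²),

to a proportional-hazards survival model through the *current value*
and *current slope* of each patient's latent trajectory,

    h_i(t) = h0(t) exp{ γ'w_i + α_v m_i(t) + α_s m_i'(t) },

with a piecewise-constant baseline hazard and baseline covariates w_i
(age, sex, cirrhosis, baseline ACLF grade, bacterial peritonitis, life
support). Around the model the package provides:

* **Clinical scoring** — UNOS MELD / MELD-Na from raw labs and
  EASL-CLIF organ-failure flags and ACLF grades (`compute_meld_na`,
  `flag_organ_failures`, `grade_aclf`, `score_lab_table`).
* **Synthetic cohorts** — a registry-like waitlist generator with
  random-intercept/slope trajectories, value-and-slope hazard,
  transplant censoring and irregular measurement times
  (`simulate_cohort`, `apply_study_filters`, `split_train_test`).
* **Estimation** — direct ML for the longitudinal submodel (`fit_lmm`)
  and the full joint likelihood in compiled code with
  posterior-adapted Gauss-Hermite quadrature (`fit_joint_model`,
  `joint_log_likelihood`, `hazard_ratio`).
* **Dynamic prediction** — updating conditional survival π(u|t) from
  each patient's history, by seeded Monte-Carlo, deterministic
  quadrature or plug-in (`predict_survival`, `rank_by_mortality`).
* **Validation** — landmarked IPCW time-dependent AUC and Brier-type
  prediction error against a last-value MELD-Na Cox benchmark, with
  paired bootstrap intervals (`dynamic_auc`, `prediction_error`,
  `bootstrap_ci`, `compare_models`).
* **Allocation experiment** — a counterfactual graft-offer re-ranking
  over the first 28 days that stratifies candidates into four priority
  groups (`offer_stream`, `simulate_allocation`, `classify_priority`).
* **Driver** — `run_experiment()` chains
  simulate → filter → 67/33 split → fit → validate → allocate and
  writes result tables plus a seed-complete manifest.

## Worked example

```r
library(meldjm)

compute_meld_na(bilirubin = 4.8, creatinine = 1.2, inr = 1.9,
                sodium = 129, dialysis = TRUE)
#>   meld meld_na bili_used creat_used inr_used na_used
#> 1   33      35       4.8          4      1.9     129

flag_organ_failures(bilirubin = 13, creatinine = 2.1, inr = 1.8,
                    he_grade = 1)[, c("liver_f", "kidney_f",
                                      "n_failures", "aclf_grade")]
#>   liver_f kidney_f n_failures aclf_grade
#> 1    TRUE     TRUE          2          2
```

Dialysis forces creatinine to 4.0 before scoring (MELD 33, raised to 35
by the sodium adjustment); bilirubin 13 mg/dl and creatinine 2.1 mg/dl
are two organ failures, hence ACLF grade 2.

The hazard-ratio calculator ships preloaded with the published
registry-fit multipliers for worked examples:

```r
pub <- published_coefficients()
hazard_ratio(pub, value = 1)                     # per +1 MELD-Na point
#> [1] 1.15
hazard_ratio(pub, covariates = list(aclf3 = 1))  # ACLF-3 vs no ACLF
#> [1] 5.9
```

A small end-to-end experiment on a synthetic cohort:

```r
res <- run_experiment(experiment_config(
  n_patients = 500, seed = 1, n_boot = 0, n_segments = 3,
  surv_covariates = c("age_c", "female", "aclf1", "aclf2", "aclf3")))

subset(res$validation, model == "aclf_jm" & landmark == 0,
       select = c(landmark, horizon, auc, pe, n_at_risk, auc_diff))
#>   landmark horizon       auc        pe n_at_risk    auc_diff
#> 1        0      28 0.8985927 0.1038126       165 0.014441796
#> 3        0      90 0.8698774 0.1547035       165 0.006695169

round(exp(res$fit$alpha_value), 3)
#> [1] 1.162

res$allocation$summary[, c("group", "n", "pct_death_28d", "median_meld_na")]
#>         group   n pct_death_28d median_meld_na
#> 1        both  52      32.69231             36
#> 2     jm_only  23      56.52174             31
#> 3 meldna_only  23      30.43478             35
#> 4     neither 402      14.67662             19
```

Reading the output: on the held-out third of the cohort the joint model
discriminates 28-day mortality with AUC 0.899, beating the last-value
MELD-Na benchmark by 0.014 (`auc_diff`); the fitted value association
`exp(α_v) = 1.162` recovers the generator's 1.15 per MELD-Na point. In
the allocation experiment the two rules disagree on 23 + 23 candidates
(equal by construction under a shared offer stream); the candidates
only the joint model would have prioritized had *lower* MELD-Na scores
(median 31 vs 35) but *higher* 28-day mortality (57% vs 30%) — exactly
the patients a snapshot score under-serves.

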