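---
title: "Joint modelling of MELD-Na trajectories and waitlist survival: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of MELD-Na trajectories and waitlist survival: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Liver grafts are allocated to waitlist candidates by the MELD-Na score,
an integer 6-40 computed from bilirubin, creatinine, INR and serum
sodium. The score is a snapshot: allocation uses only the most recent
measurement and discards the trajectory that led there. For patients
with acute-on-chronic liver failure (ACLF) — acute decompensation with
one or more failing organ systems — disease severity can change within
days, and two patients with the same current MELD-Na but very different
rates of change carry very different short-term mortality. `meldjm`
implements the full modelling chain for this problem: clinical scoring,
a joint longitudinal-survival model whose hazard depends on both the
*current value* and the *current slope* of the latent MELD-Na
trajectory, dynamic conditional survival prediction, landmarked
validation against the last-value benchmark, and a counterfactual
graft-offer re-ranking experiment.

## Clinical scoring

`compute_meld_na()` implements the UNOS laboratory MELD
(`10 * (0.957 ln Cr + 0.378 ln Bili + 1.120 ln INR + 0.643)`, labs
floored at 1.0, creatinine capped at 4.0 mg/dl and set to 4.0 under
renal replacement therapy, rounded, bounded to [6, 40]) and the sodium
adjustment (`MELD + 1.32 (137 - Na) - 0.033 MELD (137 - Na)` for
MELD > 11, sodium clamped to [125, 137]). These constants are an
external standard; they live in one place (`meld_constants()`) so a
different dialect can be swapped in.

`flag_organ_failures()` encodes the EASL-CLIF organ-failure definitions
as usable on registry data: liver failure bilirubin >= 12 mg/dl, kidney
failure creatinine >= 2.0 mg/dl or renal replacement, cerebral failure
encephalopathy grade 3-4, coagulation failure INR >= 2.5, with
mechanical ventilation standing in for respiratory failure and
life-support dependency for circulatory failure (blood-gas and
vasopressor detail is not recorded by the registry; this surrogate use
is standard in registry analyses and carries the usual
misclassification caveat). All thresholds are inclusive. Grading
(`grade_aclf()`) follows the EF-Clif patterns, including the subrules
the headline definitions leave implicit: a single kidney failure is
grade 1; a single cerebral failure is grade 1 only with kidney
dysfunction (creatinine 1.5-1.9 mg/dl); any other single failure is
grade 1 with kidney and/or cerebral dysfunction (encephalopathy grade
1-2); two failures are grade 2; three or more are grade 3.

## The joint model

For patient $i$ with measurements $y_{ij}$ at times $t_{ij}$ (days since
listing):

$$y_{ij} = m_i(t_{ij}) + \varepsilon_{ij}, \qquad
  m_i(t) = x_i(t)^\top\beta + b_{0i} + b_{1i}t, \qquad
  \varepsilon_{ij} \sim N(0, \sigma^2),\;
  b_i \sim N(0, D)$$

$$h_i(t) = h_0(t)\,\exp\{\gamma^\top w_i + \alpha_v\, m_i(t)
  + \alpha_s\, m_i'(t)\}$$

The fixed time basis $x_i(t)$ is linear by default, optionally a natural
cubic spline (truncated-power construction with a linear tail, interior
knots at quantiles of the observation times — 33rd/67th percentiles for
the default two knots) so fast non-linear deterioration can be
captured; random effects stay intercept + linear slope, which keeps the
random-effects integral two-dimensional. Slopes are always analytic
basis derivatives, never finite differences. Baseline covariates $w_i$
follow registry practice: age (centred at 56), female sex, cirrhosis
etiology, baseline ACLF grade indicators, bacterial peritonitis and
life-support dependency. The baseline hazard $h_0$ is piecewise
constant with knots at death-time quantiles (default 7 segments):
segment integrals are then closed-form up to the trajectory exponent
and the observed-information standard errors are honest.

MELD-Na is treated as continuous despite integer reporting; the
residual term absorbs the rounding. One measurement per patient
suffices for a prediction; more measurements tighten the posterior.

### Likelihood and quadrature

The per-patient likelihood is an integral over $b_i$ of (Gaussian
longitudinal density) x (survival likelihood). Because the longitudinal
factor is conjugate to the random-effect prior, the integrand
factorizes *exactly* as

$$f(y_i)\; E_{b \sim N(\mu_i, \Sigma_i)}\left[f(T_i, \delta_i \mid
b)\right],$$

where $N(\mu_i, \Sigma_i)$ is the closed-form posterior of $b_i$ given
the measurements alone. The code (RcppArmadillo) evaluates the first
factor analytically and the expectation by a tensor Gauss-Hermite rule
centred and scaled by that posterior — an adaptive rule at no extra
cost. Nine points per dimension are the default; refining 9 to 25
moves the fitted log-likelihood by less than 1e-3 on the default
synthetic cohort (asserted in the tests). Cumulative hazards use
Gauss-Legendre nodes per baseline segment, with long segments
subdivided into chunks of at most 10 days: steep trajectories make the
hazard integrand sharply peaked, and an unsubdivided rule on a long
segment can be non-monotone in the upper limit.

Estimation maximizes this likelihood by BFGS over all parameters
($\beta$, log-Cholesky of $D$, $\log\sigma$, $\gamma$, $\alpha_v$,
$\alpha_s$, log segment heights), started from a two-stage fit: the
longitudinal model alone (direct ML on the closed-form marginal
likelihood, $\beta$ profiled by GLS), then a time-dependent Cox fit on
the empirical-Bayes fitted value and slope. A seeded random start is
available for multi-start checks; both starts reach the same optimum on
the test cohorts. Standard errors come from the numerically
differentiated observed information at the optimum.

### Dynamic prediction

Conditional survival for a patient with history through landmark $t$ is

$$\pi_i(u \mid t) = E\left[\frac{S_i(u \mid b)}{S_i(t \mid b)} \,\middle|\,
\mathcal{Y}_i(t), T_i > t\right]
= \frac{E_{N(\mu_i,\Sigma_i)}[S_i(u \mid b)]}
       {E_{N(\mu_i,\Sigma_i)}[S_i(t \mid b)]},$$

the second equality because conditioning on $T_i > t$ multiplies the
measurement posterior by $S_i(t\mid b)$, which cancels. Three modes are
provided: seeded importance sampling with a multivariate $t(4)$
proposal centred at the posterior (default, 200 draws, with a
weighted-percentile Monte-Carlo band), deterministic Gauss-Hermite, and
a first-order plug-in at the empirical-Bayes mode (fastest; used for
large ranking sweeps). All modes work in log space so the ratio stays
defined when survival underflows. $\pi(t\mid t) = 1$ exactly and curves
are non-increasing.

## The synthetic cohort

No public waitlist registry with repeated MELD-Na is available, so
every downstream stage is exercised on synthetic cohorts with exactly
the structure the model assumes, generated by `simulate_cohort()`.
Defaults were fixed once to mimic a US-registry-like population:

* true association and covariate effects from the published model's
  hazard-ratio equation: value 1.15 per point; slope 1.02 per
  point/30 days (the published slope unit is unstated; this reading —
  0.594 per point/day internally — is recorded, not asserted); age 1.38
  per decade (per year is implausible); female 0.75; cirrhosis 0.95;
  ACLF grades 1.06 / 1.98 / 5.90; SBP 1.18; life support 1.35;
* trajectory marginals approximating the registry's listing MELD-Na
  medians by grade (intercept 16, grade shifts +11/+16/+20, intercept
  SD 5.5, slope SD 0.15 points/day, residual SD 2);
* baseline ACLF grade mix 66.7 / 15.9 / 10.3 / 7.1 percent and an
  etiology mix matching the registry table;
* constant baseline hazard 2e-4/day, independent transplant censoring
  at 0.006/day, other removal at 0.002/day, administrative horizon 365
  days;
* measurement gaps lognormal with median 7 days (the registry cadence
  is unpublished; this is a modelling choice, not a data fact).

Death times are drawn by inverse-transform sampling on the cumulative
hazard accumulated by the trapezoid rule on a 0.25-day grid, which is
auditable against the closed form when the hazard is constant — the
tests do exactly that via a Kolmogorov-Smirnov check at n = 5000. A
"registry mode" rounds observations to integers in [6, 40]; the
continuous mode keeps the raw Gaussian observation for clean parameter
recovery. An optional severity-dependent transplant intensity exists to
stress-test the metrics; the default is independent, matching the
censor-at-transplant analysis convention.

What the generator does *not* emulate: informative measurement timing
(sicker patients are measured more often in reality), lab-level
trajectories consistent with a given score path, exception points,
re-listing, and geographic allocation. Passing tests therefore show
correctness of the machinery under the model's own assumptions, not
transportability to real registry data — the printed registry AUC
magnitudes are not reproducible here and are not targeted.

## Validation metrics

`dynamic_auc()` is the cumulative-case / dynamic-control
time-dependent AUC with inverse-probability-of-censoring (IPCW)
weights: cases die in $(t, t+h]$, controls survive past $t+h$, subjects
censored inside the window contribute through Kaplan-Meier censoring
weights rather than being dropped (dropping them is optimistically
biased). With no censoring it reduces to the hand-countable
concordant-pair fraction; ties count one half. `prediction_error()` is
the IPCW Brier score for the survival indicator at $t+h$. Several
estimator conventions exist for both quantities; these are the standard
IPCW forms, and they sit behind a small interface so variants can be
added. Landmarks 0 / 2 / 7 / 14 days
and horizons 28 / 90 days form the default grid. The benchmark scores
patients by a Cox fit on the most recent MELD-Na at the landmark — the
current allocation logic, which ignores earlier history. Confidence
intervals and AUC-difference p-values use a paired patient-level
bootstrap (both models evaluated on the same resamples).

## The allocation experiment

`simulate_allocation()` replays a stream of graft offers over the first
28 days. Only the offer count of the study period is published, so
offer times default to uniform order statistics on (0, 28], seedable; a
vector of real offer times can be supplied. At each offer the active
candidates (not yet transplanted in the simulation, not yet dead or
removed — keeping dead patients would inflate the prioritized sets) are
ranked by the rule under study and the top candidate is transplanted
and removed. The joint-model rule recomputes predictions at every offer
time by default (a frozen-at-baseline mode exists for comparison,
since either reading of the original design is defensible). Ties break
on longer waiting time, then lexicographic id, so runs are
deterministic. With a shared offer stream the two discordant groups
("joint-model only" and "MELD-Na only") have equal size by
construction; `classify_priority()` reports the four-group partition
with registry-style group descriptives. This exercise deliberately does
not represent the complex reality of liver allocation (blood groups,
geography, refusals); it isolates the effect of the scoring rule.

## Numerical choices and edge cases

* $\sigma$ is floored at 5e-4 during longitudinal estimation: below
  that the marginal covariance is numerically singular and the surface
  flat for any realistic data. Noise-free data hit the floor and are
  interpolated to ~1e-4.
* Non-PSD random-effect covariances, non-positive hazards, empty
  histories, landmarks before the first measurement, unknown covariate
  names, and windows without events or survivors all raise immediate,
  named errors rather than degraded numbers; an AUC without events is
  an error, never silently 0.5.
* Patients whose simulated trajectory diverges (log-hazard exponent
  above 50) are redrawn and counted in the output.
* Hazard-overflow inside the fitted likelihood follows a rescaled
  log-sum-exp path; a still-non-finite contribution aborts with the
  offending patient id.

## Problem sizes in the shipped checks

The test suite exercises parameter recovery at 1000 patients
(~5 measurements each) with 20 replicates for interval coverage,
discrimination comparisons on a 3000-patient held-out cohort against a
1000-patient training fit, and the allocation experiment at 1000
patients with 150 offers. These sizes give stable Monte-Carlo behaviour
at desk scale; the qualitative conclusions (joint model dominates the
last-value benchmark when slope effects are active; the two coincide
when they are not) are insensitive to them.

## Known limitations

Single longitudinal outcome (no joint bilirubin/INR/creatinine
trajectories); Gaussian iid residuals (no autocorrelation or heavy
tails); transplant treated as non-informative censoring rather than a
competing risk; no delayed entry (all patients enter at listing); no
CLIF-C ACLF score (the registry lacks the leucocyte counts it needs);
the published coefficients ship as a worked-example fixture only and
are never used as fitting targets.
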