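---
title: "Doubly robust comparative effectiveness from coded EHR event streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubly robust comparative effectiveness from coded EHR event streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ehrdr` implements a new-user, active-comparator comparative-effectiveness
analysis of second-line type 2 diabetes (T2D) therapies on a fixed-horizon
composite outcome (heart-failure hospitalization or death within five
years), driven entirely by longitudinal coded EHR event streams. This
vignette describes the statistical model, its assumptions, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, the numerical choices, and known limitations. It states no
empirical result that the package's test suite does not itself compute.

## The estimation problem

Patients treated with metformin initiate exactly one of two second-line drug
classes (arm $A \in \{0, 1\}$, e.g. insulin vs sulfonylureas). For patient
$i$ with baseline covariates $X_i$, follow-up runs from the initiation
(index) date to the first of: HF hospitalization, death, or the last medical
encounter (censoring). With $\tau$ = 1826 days (five years), the observables
are the follow-up time $\tilde T_i$, the event indicator $\delta_i$, the
horizon status $Y_i^\tau = 1\{\delta_i = 1,\ \tilde T_i \le \tau\}$, and its
completeness indicator $\Delta_i^\tau = 1\{Y_i^\tau = 1 \text{ or } \tilde
T_i \ge \tau\}$. Two marginal estimands are targeted:

* the **risk difference** $\psi_1 - \psi_0$ with
  $\psi_a = P(Y^\tau = 1 \mid \mathrm{do}(A = a))$, and
* the **event-free survival ratio** $S_1(\tau) / S_0(\tau)$.

### Nuisance models

1. **Propensity** $\pi(x) = P(A = 1 \mid X = x)$: adaptive-LASSO logistic
   regression, predictions truncated to $[\varepsilon, 1 - \varepsilon]$
   ($\varepsilon = 0.01$ by default).
2. **Outcome regression** $m_a(x) = P(Y^\tau = 1 \mid A = a, X = x)$:
   adaptive-LASSO logistic regression on $(A, X)$ with the treatment column
   unpenalized (the effect of interest is never shrunk away), fit on rows
   with known horizon status and weighted by the inverse censoring
   probabilities.
3. **Conditional survival**: a Lin–Ying additive hazards model
   $\lambda(t \mid A, X) = \lambda_0(t) + \theta A + \beta^\top X$ fit by
   the closed-form least-squares estimating equations on $[0, \tau]$, with
   adaptive-LASSO shrinkage of the covariate block via the equivalent
   penalized quadratic program ($\theta$ unpenalized by default), and a
   Breslow-type cumulative baseline. Coefficients are events per
   person-year; time is internally measured in years (days / 365.25).
4. **Censoring**: a Kaplan–Meier estimate $\hat K(t)$ of the
   last-encounter (censoring) distribution, pooled over arms under the
   independent-censoring assumption, always evaluated at left limits
   $\hat K(t-)$; weights $\Delta_i^\tau / \hat K(\min(\tilde T_i, \tau)-)$
   with a positivity floor (0.05) below which evaluation is an error.

### The doubly robust estimators

$$\hat\psi_a = \frac1n \sum_i \left[ \hat m_a(X_i) +
  \frac{1\{A_i = a\}}{\hat\pi_a(X_i)}
  \frac{\Delta_i^\tau}{\hat K(\min(\tilde T_i,\tau)-)}
  \left(Y_i^\tau - \hat m_a(X_i)\right) \right]$$

$$\hat S_a(\tau) = \frac1n \sum_i \left[
  \frac{1\{A_i = a\}}{\hat\pi_a(X_i)}
  \frac{\Delta_i^\tau (1 - Y_i^\tau)}{\hat K(\min(\tilde T_i,\tau)-)} +
  \left(1 - \frac{1\{A_i = a\}}{\hat\pi_a(X_i)}\right)
  \hat S(\tau \mid a, X_i) \right]$$

Both are augmented inverse-probability-weighted (AIPW) estimators: each is
consistent when either the treatment/censoring models or the outcome-side
model is correct. Two exact algebraic identities anchor the implementation
and are unit-tested: with no censoring and a constant true propensity the
augmentation cancels and $\hat\psi_a$ equals the arm-$a$ sample mean; and
when the same logistic $\hat m_a$ feeds both formulas,
$\hat\psi_a + \hat S_a(\tau) = 1$ row by row (exposed as the
`survival_from_logistic` cross-check mode).

### Inference

Nonparametric patient-level bootstrap ($B = 500$ by default): the SD of
replicate points (log scale for the ratio, because additive-hazards
survival ratios are asymmetric around 1), normal-approximation confidence
intervals, and two-sided Wald p-values (null 0 for differences, 1 for
ratios). The penalties are **fixed at the full-data selection** across
replicates and only the fits (including the adaptive weights) are redone —
this bounds runtime and stabilizes the resampling distribution; full
re-selection is available via `reselect_lambda`. Replicates that lose an
arm or hit a censoring-positivity failure are redrawn and counted, with a
hard error past 10% of $B$: inference from a cohort that fragile would be
meaningless anyway.

## Adaptive-LASSO details

Initial estimates come from a ridge logistic (or ridge quadratic, for the
hazards model) fit at a fixed small penalty (`ridge_lambda = 0.01`);
adaptive weights are $w_j = 1/|\hat b_{\text{ridge},j}|^\gamma$ with
$\gamma = 1$. Covariates are standardized internally and coefficients
reported on the original scale; the intercept and (in outcome models) the
treatment column are unpenalized. The penalty grid is geometric over four
orders of magnitude. Cross-validation is **honest**: the ridge initial
estimator, hence the weight vector, is recomputed inside every training
fold — computing weights on the full data leaks the held-out outcomes into
the penalty structure and systematically favors over-rich models.

Two selection rules are provided. `selection = "min"` (default) takes the
exact CV-loss minimizer; `"1se"` takes the sparsest penalty within one
cross-validation standard error of it. The trade-off is real and measurable
in this package's own tests: the exact minimizer is not
selection-consistent (on a pure-null design it retains small spurious
coefficients in roughly half of runs, while the 1-SE rule selects the empty
model essentially always — the null-design test asserts the latter), but
the 1-SE rule over-shrinks genuinely needed confounders in the propensity
model, visibly degrading weighted covariate balance. Since the estimators
are doubly robust and the balance/bias criteria are the analysis-facing
ones, the minimizer is the default and the 1-SE rule is a switch.

At a fixed penalty the logistic solve is an in-package IRLS/coordinate-
descent (compiled kernel): bootstrap inference refits every nuisance
hundreds of times, and this path is roughly an order of magnitude faster
than a generic path solver while agreeing with `glmnet` at the same penalty
to ~1e-7 and with `glm` at $\lambda = 0$ to ~1e-6 (both asserted in tests).
Penalty selection itself uses `glmnet` path fits inside the CV loop.

## Numerical choices

* **Time units**: dates parse to integer day offsets (epoch 2010-01-01);
  intervals are whole days; hazard-model time is years = days/365.25. Five
  years is $\tau$ = 1826 days = 4.9993 years.
* **Gap rule**: medication pairing uses a closed interval, 30–180 days, over
  *all* ordered same-ingredient pairs; the earliest qualifying pair's first
  code dates the episode.
* **Strict eligibility comparisons**: age > 18 years; metformin initiation
  strictly pre-index; an encounter dated more than 365 days before and one
  more than 30 days after index (encounters at exactly those offsets fail).
* **Windows**: recent = $[\text{index}-365, \text{index})$, history
  = everything strictly earlier; index-day events count in neither (no
  outcome leakage).
* **Prevalence filter**: a count column is kept iff at least
  $\lceil 0.05\,n \rceil$ patients have a nonzero count (47 of 939).
* **Imputation**: pooled-arm complete-case column means; an all-missing
  column is a hard error; equidistant lab measurements resolve to the
  later-entered row.
* **Baseline hazard**: the Breslow-type $\hat\Lambda_0$ is reported on the
  original covariate scale after isotonic projection (cumulative maximum,
  floored at zero) so the published object is nondecreasing; *predictions*
  use the unprojected standardized-scale baseline, which makes them exactly
  invariant to affine rescaling of covariates (the original-scale
  projection is not affine-equivariant). Predicted survivals are clipped to
  $[0,1]$, with a log note when clipping exceeds 1% of rows.
* **Degenerate guards**: zero-variance columns in a (resampled) design are
  dropped from the Lin–Ying system with zero coefficients; $\hat S_0$ is
  floored at $10^{-6}$ before forming ratios; coefficients below $10^{-12}$
  (soft-threshold boundary dust) are zeroed.
* **Determinism**: CV folds are assigned by a seeded permutation applied in
  patient-id order and the bootstrap is seeded, so estimates are invariant
  to row order and bit-reproducible for a fixed `analysis_config`.

## The synthetic world

`sim_config()` / `generate_population()` draw a population of metformin
users who initiate one of two comparator classes and render it as a coded
event stream (demographics, T2D and HF diagnoses, metformin/second-line/
switch medication pairs honoring the 30–180-day rule, labs with
missingness and decoy measurements, dictionary code counts placed in their
temporal windows, encounters, HF hospitalizations, deaths). Design choices:

* **Counts** are negative binomial (overdispersed, like real EHR code
  counts) with geometrically decaying means `count_mu * count_decay^(j-1)`,
  so the dictionary has a rare tail for the prevalence filter to remove.
* **Confounding** enters through user-set vectors: log-odds of treatment
  and additive hazard per unit count on the same features.
* **Events**: HF time is exponential with rate
  $\lambda_0 + \theta A + \beta^\top X$; death is an independent competing
  exponential; the composite is the earlier. The Monte-Carlo oracle
  (`oracle_estimands()`) integrates the closed-form composite survival
  $\exp(-(\lambda_0 + \theta a + \beta^\top X + \lambda_{\text{death}})\tau)$
  over fresh covariate draws, both arms on common draws, with MC standard
  errors; the death hazard cancels from the survival ratio, which equals
  $e^{-\theta\tau}$ exactly whenever the effect is purely additive.
* **Censoring** is the last encounter of an independent visit process whose
  endpoint is exponential (mean 30 years) truncated at a 10-year
  administrative horizon — about 15% of patients censored within five
  years. No censoring rate is reported for the real data; this is a free
  choice of the synthetic world, made once.
* **Switchers**: a post-index Bernoulli flag (default 10%) injects a
  qualifying pair of another comparator class, exercising the per-protocol
  path.
* Hazards are kept nonnegative by reject-and-resample of covariate draws,
  with a hard failure after a bounded number of rounds (an infeasible
  configuration should fail loudly, not silently truncate).

What the generator does **not** emulate — hence what a green test does not
establish: informative censoring (censoring is marginally independent, so
IPCW is correct by construction and the tests cannot detect sensitivity to
its violation); time-varying hazards or effects; clinical text;
measurement error in codes; multi-institution heterogeneity; and the
upstream phenotyping and chart-review processes (T2D status and HF
hospitalization labels enter as given events).

The generator's per-patient bookkeeping doubles as ground truth: the cohort
builder is required (and tested) to recover index dates, arms, follow-up,
event indicators, eligibility and switch flags for 100% of patients from
the rendered event stream, and a tabular fast path
(`bookkeeping_cohort()` / `bookkeeping_covariates()`) lets simulation
studies skip re-parsing events once that equivalence is established.

## Analysis styles and diagnostics

The primary analysis is intent-to-treat (post-index switching ignored); the
per-protocol sensitivity drops switch-flagged patients before any fitting.
Balance diagnostics report standardized mean differences
$(\bar x_1 - \bar x_0)/\sqrt{(s_1^2 + s_0^2)/2}$, unweighted and under ATE
inverse-propensity weights, flagged at the conventional 0.1. The pipeline
(`run_analysis()`, CLI `ehrdr`) writes the cohort with per-patient
exclusion reasons (first-failure attribution, in rule order), balance
tables, results JSON and a run manifest with seeds and counts; attrition
must account for every input patient exactly, which is asserted at run
time.

## Limitations

* The additive hazards model can predict survivals outside $[0,1]$ for
  extreme covariates; clipping is logged but is still an approximation.
* Min-CV penalty selection retains occasional spurious near-zero
  coefficients (see above); neither rule is uniformly superior.
* The bootstrap fixes the selected penalty across replicates, so the CIs do
  not propagate selection uncertainty; `reselect_lambda = TRUE` does, at
  substantial cost.
* Fixed-horizon estimands only; no sequential-treatment or time-varying
  analyses.
* With very strong confounding, propensity truncation at $\varepsilon$
  trades bias for variance; the truncation bound is configurable and
  reported.
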