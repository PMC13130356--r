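---
title: "Biological age, dietary indices, and design-based inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biological age, dietary indices, and design-based inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdmcohort)
```

This vignette is the package's account of its own methods: the estimators,
the synthetic cohort generator that provides ground truth for them, the
numerical choices, and the limits of what the validation demonstrates.

## The study design being modeled

The analysis pattern is a cross-sectional survey study: adults over 45
from a stratified multi-stage sample, a binary exposure (any antibiotic
prescription in the past 30 days, nonusers as reference), two binary
outcomes (accelerated biological aging; self-reported diarrhea), two
nested covariate sets (Model 1: age, sex, race/ethnicity, marital status,
income–poverty ratio, smoking, alcohol, energy intake, BMI; Model 2
additionally CRP and white blood cell count as infection markers), and
effect-modification strata defined by median splits of two dietary
indices. All models are survey-weighted logistic regressions with
design-based variance.

The order of operations is fixed: weight pooling, exclusions, KDM
training and scoring, index scoring, median splits, then models. Medians
and CDAI references are computed on the age-restricted analytic sample,
and every model — overall or stratified — reuses the same KDM and index
values, computed once.

## Klemera–Doubal biological age

The estimator combines per-biomarker regressions on chronological age
into a precision-weighted composite plus a chronological anchor:

$$\mathrm{KDM} \;=\; \frac{\sum_i (x_i - q_i)\,k_i/s_i^2 \;+\;
\mathrm{CA}/s_{BA}^2}{\sum_i k_i^2/s_i^2 \;+\; 1/s_{BA}^2}.$$

Assumptions worth stating explicitly: biomarker trajectories are linear
in age with homoscedastic residuals; biomarkers are conditionally
independent given biological age (their weights $k_i^2/s_i^2$ are derived
marginally); and a single scalar latent "biological age" shifts all
markers coherently along their age slopes.

Decisions the estimator's definition leaves open, and what this package
does:

* **RMSE divisor.** $s_i$ uses $\sqrt{RSS/n}$ by default;
  $\sqrt{RSS/(n-2)}$ is available (`rmse_divisor = "n-2"`). At survey
  scale the difference is negligible; at toy scale tests pin the default.
* **RMSE floor.** A deterministic trajectory gives $s_i = 0$ and an
  unevaluable $1/s_i^2$; fitted RMSEs are floored at $10^{-8}$ (biomarker
  units). The mean-trajectory identity (a record on every fitted
  trajectory scores its own CA) holds exactly for any positive $s_i$, so
  the floor does not perturb it.
* **$s_{BA}$.** No universally agreed estimator exists. The default is a
  variance decomposition: with the unscaled biomarker-only estimate
  $BA_E$, take $s_{BA}^2 = \operatorname{Var}(BA_E - CA) - 1/\sum_i
  k_i^2/s_i^2$, floored at $10^{-6}$ years², i.e. the dispersion of
  biological-age deviations after removing estimation noise. That matches
  the semantics of "variance in chronological age explained by the
  biomarker set". A fixed user-supplied `s_ba` is accepted for strict
  reproduction of other implementations; the method label is serialized
  with the model.
* **Zero-slope biomarkers** are retained with zero weight and a warning,
  rather than rejected — deleting them provably leaves scores unchanged,
  and keeping them preserves the declared panel.
* **Training sample.** The model is trained on the same complete-case
  analytic sample it scores; an external training table can be supplied
  to `fit_kdm()` via its cohort argument for transportability studies.
* **Acceleration threshold.** `accelerated` means a positive residual of
  KDM age on CA. The zero cutoff is the natural residual split (it makes
  prevalence ≈ 1/2 by construction) and is configurable
  (`analysis_config(accel_threshold = ...)`).

Affine invariance — rescaling any biomarker as $x' = a x + b$ and
refitting leaves every score unchanged — follows because $(x-q)k/s^2$ and
$k^2/s^2$ are invariant under the induced change of $(q, k, s)$; the test
suite verifies it numerically, together with exact agreement between the
vectorized implementation and a naive per-record evaluation of the
formula.

## Dietary indices

**DI-GM** is pure configuration: fourteen components (ten beneficial,
four unfavorable), each with one rule — score 1 at/above the sex-specific
median for beneficial, below it for unfavorable, or the fixed rule "under
40% of energy from fat" for the high-fat component. Green tea is defined
but not scorable in NHANES-like inputs, so thirteen components contribute
and the attainable range is 0–13 (verified by enumeration). Because the
roster is a data frame, corrections to component membership or rules
require no code change.

**CDAI** standardizes six antioxidant intakes against sex-specific
references. The scale is the standard error of the mean by default,
following the index definition adopted here; much of the CDAI literature
uses the SD, so `scale_kind = "SD"` is available and the choice is
recorded on the reference object. Under the SE convention the scores have
much larger magnitude (deviations are divided by $SD/\sqrt{n}$) and a
skewed distribution — the sample mean is still exactly zero when
references come from the same sample, which is what the median split
consumes, so the convention does not affect stratification logic.

**Median splits** use the survey-weighted median by default (the split
should respect the design), with an unweighted option. Two conventions
are fixed deterministically: a value exactly at the median is labeled
*high*, and the weighted median interpolates — when the cumulative weight
hits exactly half the total at an order statistic, the median is the
midpoint of that value and the next, so equal weights reproduce the
textbook even-$n$ sample median.

## Design-based logistic regression

Point estimates maximize the weighted pseudo-log-likelihood by IRLS.
Weights are normalized to mean one internally — estimates and the
sandwich are invariant to the weight scale, and the convergence criterion
(score sup-norm below $10^{-8}$, at most 100 iterations) becomes
scale-free. Fitted probabilities are clamped to $[10^{-10},
1-10^{-10}]$ inside the working response only.

The covariance is the stratified-cluster Taylor linearization: per-record
scores $w_j x_j (y_j - p_j)$ are totaled per PSU, centered within
stratum, and their outer products accumulated with the per-stratum factor
$n_h/(n_h - 1)$, then sandwiched between inverse information matrices.
With equal weights and one record per PSU in a single stratum this equals
the HC0 robust sandwich times $n/(n-1)$, which the tests verify against
an independent reference implementation.

Further conventions:

* **Singleton-PSU strata** contribute their score total centered at the
  grand mean of all PSU totals (the "adjust" convention) instead of
  erroring; the event is logged.
* **Confidence intervals** use the normal 1.96 quantile by default, with
  `ci = "t"` using the t distribution on the design degrees of freedom
  (PSUs minus strata). For designs with few PSUs the t interval is the
  appropriate choice and is what survey practice recommends; the
  package's default design (90 PSUs) leaves the two nearly
  indistinguishable, and the replicate-coverage check in the acceptance
  suite verifies 95% intervals cover a planted odds ratio at close to
  nominal rate.
* **Separation** is declared when any coefficient exceeds 15 in absolute
  value — under (quasi-)complete separation the pseudo-likelihood
  gradient itself vanishes as coefficients diverge, so the magnitude, not
  the gradient, is the reliable trigger. The error names the offending
  term.
* **Missing data** are handled strictly complete-case on the model frame,
  with the dropped count reported.

## The synthetic cohort generator

The generator exists so that every downstream stage can be validated by
parameter recovery. It emulates:

* **Design geometry:** 45 strata × 2 PSUs by default — the scale of three
  pooled survey cycles — with balanced assignment so every PSU is
  populated, and i.i.d. lognormal weights (sdlog 0.6) independent of
  everything else, which keeps weighted estimators consistent so recovery
  tests are valid. Design degrees of freedom also stabilize the variance
  estimator; with very few strata the sandwich is noisy and normal-quantile
  intervals undercover.
* **Biomarkers:** linear trajectories in *biological* age with Gaussian
  residuals, in clinical units with slopes in the range of published age
  gradients.
* **Diet:** sex-specific lognormal intakes for twelve DI-GM food groups
  and six CDAI nutrients, and a Beta-distributed fat energy share
  centered near 0.34 so the 40% rule binds for a realistic minority.
* **Exposure and outcomes:** logistic models with intercepts calibrated
  numerically (by `uniroot`) so marginal prevalences hit their targets —
  8% antibiotic use, 8% diarrhea, and exactly 1/2 for accelerated aging,
  which is a residual split by definition.
* **Missingness:** MCAR per cell. Complete-case exclusion — the analysis
  policy — is only defensible under MCAR, so the simulator matches the
  assumption the analysis makes.
* **Reproducibility:** one stream per cohort, with purpose-keyed
  substreams (design, demographics, diet, exposure, outcomes, biomarkers,
  missingness) so that editing one part of the config does not scramble
  unrelated columns.

**The planted accelerated-aging effect** is the one subtle construction.
Planting an odds ratio directly on the *downstream* KDM-acceleration
indicator would be circular (the generator would need the estimator).
Instead the binary accelerated status is drawn from its logistic model,
and each participant's latent biological age is shifted by $\pm(g +
|N(0,\sigma)|)$ years in the corresponding direction ($g = 14$, $\sigma =
2$ by default). The downstream residual split then recovers the planted
status whenever the KDM estimator's composite noise is smaller than the
gap. Two consequences, stated plainly:

* The default biomarker panel is deliberately **higher-signal than real
  blood chemistry** (each marker predicts age to roughly ±11 years;
  real panels are noisier). This keeps planted-versus-recovered
  concordance above 99%, so recovery tests measure the pipeline, not the
  irreducible noise of a weak panel. The one near-flat marker (WBC)
  exercises the near-zero-weight path.
* With a planted exposure effect, the marginal biomarker-on-age slope
  acquires a real indirect component (age → exposure probability →
  acceleration → biomarkers), so trajectory-linearity checks are run
  under null planted effects, where the latent shift is symmetric and
  independent of age.

When an outcome's planted effect is stratum-specific, the generator
derives each participant's low/high dietary stratum with the package's
own scoring functions — weighted sex-specific medians on the over-45
subsample, exactly the construction the pipeline applies — so planted and
analyzed strata coincide by construction rather than approximately.

**What the generator does not emulate,** and therefore what passing tests
do *not* show about real data: survey file layouts and real sampling
fractions or nonresponse adjustment; non-Gaussian or age-nonlinear
biomarker trajectories; informative (non-MCAR) missingness; measurement
error and self-report bias in exposure and outcomes; confounding
structure beyond the generated covariates (recovery tests certify the
estimators under a correctly specified model, not causal validity); and
the derivation of a diarrhea indicator from bowel-health questionnaire
items, which real-data users must define themselves.

## Problem sizes and runtime envelope

Validation uses desk-scale sizes chosen to keep Monte-Carlo error
comfortably inside the assertions: single-cohort recovery experiments use
n = 50,000 generated directly on the over-45 age range (so all records
are analytic and none are spent on the age-floor exclusion); interval
coverage uses 200 replicate cohorts of n = 5,000; trajectory and
parameter-recovery checks use n = 10,000–20,000; algebraic identities use
hundreds of records. A full study run on n = 50,000 takes a few seconds
on one CPU.

## Known limitations

* The `s_BA` estimator is one defensible choice among several; results
  that depend on the absolute scale of KDM acceleration (not on its sign
  or ranks) can differ across conventions. The serialized model records
  which was used.
* Variance estimation offers no replicate-weight (BRR/jackknife) option,
  no finite-population corrections, and no multiple imputation; these are
  out of scope by design.
* Categorical covariates enter as reference-coded indicators with the
  first level as reference; real-data users should supply their own
  coding if a different reference is needed.
* The stratified (effect-modification) models adjust for the Model 1
  covariate set; Model 2 in the primary analysis serves as the
  infection-marker sensitivity adjustment.
* The DI-GM roster and rules ship as defaults that match the 0–13
  documented range; users with different component definitions should
  edit the configuration rather than the code.
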