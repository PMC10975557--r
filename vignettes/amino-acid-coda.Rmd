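---
title: "Modelling glycemic biomarkers from dietary amino-acid composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glycemic biomarkers from dietary amino-acid composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacoda)
library(dplyr)
```

## The problem

Dietary protein is a mixture of amino acids whose proportions are mutually
constrained: eating relatively more of one amino acid necessarily means
relatively less of the others. Entering single amino-acid intakes as
ordinary covariates in a regression therefore confounds "more leucine" with
"less of everything else" in an uncontrolled way. `aacoda` treats the
18-part amino-acid intake vector (percent of total amino acids) as a
*composition* and analyses it in the Aitchison geometry: all information is
carried by log-ratios, and effects are expressed as *substitutions* — what
happens to a fasting glycemic biomarker when a fixed slice of total amino
acids is moved from one component to another.

The outcomes modelled are fasting plasma glucose (mg/dL, raw scale) and
fasting serum insulin, HOMA-IR and HOMA-β, which are right-skewed and
modelled on the natural-log scale. The HOMA indices are the usual fasting
surrogates of insulin resistance and β-cell function:

$$\mathrm{HOMA\text{-}IR} = \frac{I\,[\mu U/mL] \times G\,[mmol/L]}{22.5},
\qquad
\mathrm{HOMA\text{-}\beta} = \frac{20\, I}{G\,[mmol/L] - 3.5}\ [\%],$$

with glucose converted as $G[mmol/L] = 0.05551 \times G[mg/dL]$. HOMA-β has
a pole at 3.5 mmol/L (≈ 63 mg/dL); the package treats inputs at or below
the pole as an error rather than clipping, because fasting values that low
signal hypoglycemic-range data that should not be silently summarised.

## Pivot coordinates and the repeated-ordering sweep

A composition $x = (x_1,\dots,x_D)$, closed to 100, is mapped to centred
log-ratios $\operatorname{clr}(x)_i = \ln(x_i/g(x))$ and then to isometric
log-ratio (ilr) *pivot coordinates* $z = B\,\operatorname{clr}(x)$, where
$B$ is the orthonormal $(D-1)\times D$ pivot contrast matrix of a chosen
component ordering. The first coordinate is, up to sign,

$$z_1 = \sqrt{\tfrac{D-1}{D}}\,
\ln\frac{x_{(1)}}{g(x_{(2)},\dots,x_{(D)})},$$

the log-ratio of the first-ordered component to the geometric mean of the
rest — exactly the "one component versus all others" contrast of interest.
Because only the first coordinate is interpretable this way, the regression
is repeated $D = 18$ times, rotating each amino acid into the first
position (`pivot_sweep()`). The 18 models are rotations of one another:
fitted values, residuals, $R^2$ and $\sigma^2$ are identical across
orderings, and the 18 first-pivot coefficients are a rescaled projection of
a single fit's coefficients into clr space — which is why they sum to zero
identically, a property the test suite checks on every run.

**Sign convention.** The package's default basis is the *negated* pivot
basis (`sign_convention = "reversed"`): every row of $B$ is multiplied by
−1. With this convention a positive first-pivot coefficient means that a
*higher* share of the pivot component (relative to the geometric mean of
the rest) predicts a *lower* outcome, so pivot coefficients and
substitution effects have opposite signs. The conventional
(non-negated) basis is available via `sign_convention = "standard"`; all
substantive output (fitted values, p-values, substitution effects) is
identical under either choice, only coefficient signs flip.

Adjustment covariates follow a fixed set (age, sex, BMI z-score, physical
activity, sleep, screen time, single parent, passive smoking, siblings,
energy, protein, fiber) plus any of the candidate nutrients (energy,
protein, saturated fat, fiber, glycemic load) that pass a simple-regression
screen at p < 0.05 against glucose or log insulin (`covariate_screen()`).
Sex and the binary lifestyle flags enter as 0/1; siblings (1 / 2 / ≥3) as
two dummies with one sibling as reference. Classical (non-robust) OLS
standard errors and two-sided t-tests on $n - p$ degrees of freedom are
used; no multiplicity adjustment is applied across the 18 components — the
repeated-ordering design makes the tests strongly correlated, and the
substitution analysis below is the primary summary. Variance inflation
factors (`vif_values()`) are reported as a multicollinearity check.

## Substitution effects

Effects are evaluated at the cohort's geometric-mean composition
(component-wise geometric means, re-closed; `reference_composition()`).
Two replacements of δ = 0.1 percentage points of total amino acids are
supported:

* **one-to-all** (`one_to_all_table()`): component $i$ gains δ, each of the
  other $D-1$ components loses $\delta/(D-1)$;
* **one-to-one** (`one_to_one_matrix()`): component $i$ gains δ taken
  entirely from component $j$.

δ = 0.1 is the package default because it is of the order of the
between-person SD of the component shares — a realistic dietary shift.
Both operations act additively on the percentage scale, so the total is
conserved exactly and no re-closure is needed; a replacement that would
drive a share to zero or below is rejected by name.

For a linear model the predicted difference between the perturbed and the
reference composition is an exact linear contrast: covariates and intercept
cancel, leaving $\hat\Delta = c^\top\hat\beta$ with
$c = \operatorname{ilr}(x') - \operatorname{ilr}(x)$ padded with zeros. Its
standard error is the delta-method form
$\sqrt{c^\top \widehat{\operatorname{Cov}}(\hat\beta)\, c}$, which is exact
(not an approximation) for OLS, and the reported interval is
$\hat\Delta \pm 2\,\mathrm{SE}$. We deliberately compute the SE of the
*difference* through the full coefficient covariance rather than combining
the SEs of two separate predictions, which would ignore their (near-total)
covariance; the difference is the estimand. A parametric-bootstrap
cross-check of the SE is part of the acceptance suite.

Because the contrast is a log-ratio expression, the one-to-one matrix is
only antisymmetric to first order: increasing leucine by 0.1 at the expense
of isoleucine is not the exact mirror of the reverse replacement, and the
residual $|\Delta_{ij} + \Delta_{ji}|$ shrinks as $O(\delta^2)$ — a Taylor
property the tests verify at δ ∈ {0.1, 0.01, 0.001}. Effects are local to
the reference composition and should not be extrapolated to extreme diets.

The grouped analysis (`grouped_pivot_sweep()`) amalgamates the 18 parts
into side-chain classes (BCAA, aromatic, sulfur, other) by summation and
re-closure, then proceeds identically on the 4-part composition.
Amalgamation is a projection, not an isometry: grouped results are a
coarser, not an averaged, view of the component-level analysis.

## The synthetic cohort generator

Real per-participant dietary and serum data of this kind are private, so
the package ships a generator (`generate_cohort()`) that emulates the
statistical structure the analysis assumes and carries its own ground
truth. Defaults, chosen once as the package's study conditions:

* **Composition.** Logistic-normal: log shares are multivariate normal
  with mean $\ln$(reference geometric means from `aa_reference()`) and, by
  default, diagonal covariance with $\mathrm{sd}(\log x_i)$ set to the
  reference coefficient of variation (SD / arithmetic mean, range
  ≈ 0.019–0.090). The logistic-normal family is closed under the clr
  analysis applied downstream and matches the observation that geometric
  and arithmetic means nearly coincide at these small CVs. Off-diagonal
  log-covariances can be supplied; none are assumed by default.
* **Covariates.** Independent draws matching the calibration marginals
  (52.6% male, age 163.5 ± 3.4 months, BMI 19.2 ± 2.6, zBMI −0.25 ± 0.90,
  energy 2266.4 ± 634.9 kcal, protein 14.2 ± 2.3 %E, fiber 5.5 ± 1.4
  g/1000 kcal, saturated fat 10.6 ± 2.5 %E, glycemic load 68.4 ± 22.5,
  siblings 9.5/47.5/43.0%, etc.). Energy is drawn truncated to its
  plausibility window so that clean rows survive the energy filter, which
  lifts its mean by roughly 2%; an optional knob correlates protein with
  the BCAA share for confounding stress tests, off by default.
* **Outcomes.** Glucose = 90.6 + $a^\top(\operatorname{clr}(x) -
  \mathbb{E}\,\operatorname{clr})$ + small effects of zBMI, energy, protein
  and fiber + $N(0, 5.0^2)$; the signal terms bring the total SD to ≈ 5.6
  mg/dL. The default ground-truth clr vector $a$ for glucose is −60
  (leucine), +35 (isoleucine), +25 (methionine), 0 elsewhere — sum-zero,
  with the sign pattern the method is designed to detect and magnitudes
  that give the first-pivot coefficients the same order (tens of mg/dL) as
  the analysis reports on real data. Insulin is lognormal with geometric
  mean 6.19 and log-SD 0.45 (total ≈ 0.467, implied by the calibration
  CI), with no composition effect by default; HOMA columns are derived
  through the marker formulas, never simulated directly. Glucose draws are
  resampled outside [67, 125] mg/dL (≈ ±4.5 SD) to keep every cohort above
  the HOMA-β pole and in a physiologic fasting range.
* **Exclusions.** 15 / 40 / 150 / 4 extra rows (unanswered questionnaire,
  implausible energy, missing items, disease) are injected with disjoint
  flags and internally consistent data (e.g. implausible rows really carry
  out-of-window energy), so a default run enters the filter with 1447 rows
  and analyzes exactly 1238.

What the generator does **not** emulate: food-frequency measurement error,
amino-acid cross-covariances, covariate–composition confounding (unless
enabled), school-level clustering, or any non-linearity. Passing
recovery/coverage tests on generated data therefore validates the
*estimator and its uncertainty under the assumed model*, not the substantive
findings on real cohorts.

## Numerical and design choices

* Natural logarithms throughout; shares on the 0–100 scale; δ in
  percentage points.
* Zero or negative shares are an error naming the component — dietary
  amino-acid shares are structurally positive, so no zero-imputation is
  offered.
* OLS by QR decomposition; covariance via Cholesky of $X^\top X$; rank
  deficiency is an error naming the collinear columns.
* The LMS z-score uses `expm1` so the $L \to 0$ branch is continuous to
  machine precision; reference lookup is nearest-age within ±6 months per
  sex, an error beyond that (no silent extrapolation). LMS and EER
  reference tables are user-supplied configuration; the bundled
  `synthetic_*` tables exist so examples and tests are self-contained.
* "Between" in the energy-plausibility rule is a closed interval (the
  weaker filter).
* Exclusion attribution is first-hit in the listed order; permuting the
  order never changes who is analyzed, only the per-reason bookkeeping.
* Geometric-mean CIs are the exponential of the t-based CI of the log
  mean.

## Simulation sizes used by the test suite

Deterministic properties (rotation invariance, sum-zero coefficients,
oracle equality of contrast and prediction difference) are checked on
cohorts of a few hundred rows — they hold to numerical precision at any
size. Statistical calibration uses 100 replicate cohorts of n = 1238 for
CI coverage (pooled over the 18 components, accepted in [0.92, 0.98]) and
type-I error (pooled over the 15 null components, accepted in
[0.03, 0.07]); the parametric bootstrap for the substitution SE uses 2000
replicates on one fixed cohort of n = 400. These sizes keep Monte-Carlo
error a few times smaller than the acceptance bands.

## Known limitations

* Effects are defined at (and only near) the geometric-mean composition.
* One-vs-rest pivots are the only balance system offered; no general
  sequential binary partitions.
* Classical SEs only; no robust, clustered or survey-weighted variants.
* The generator's diagonal log-covariance understates the real negative
  dependence that closure induces among shares; recovery tests pass
  because the analysis model matches the generator, which is the point of
  the exercise, not evidence about mis-specified settings.
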