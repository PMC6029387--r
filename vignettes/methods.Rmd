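---
title: "Methods: neonatal weight change and childhood cardio-metabolic tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal weight change and childhood cardio-metabolic tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadirpath)
```

## The scientific question

Newborns lose on the order of 6–7% of their birthweight in the first days of
life before regaining it. `nadirpath` implements an analysis pipeline that
(1) estimates each newborn's weight-change percentage (NWC) at the population
weight nadir from sparse early-life weight data, and (2) asks whether NWC is
associated with cardio-metabolic traits (glucose, LDL-C, triglycerides, waist
circumference, systolic and diastolic blood pressure) measured at ages 4 and
7 years, directly or mediated by the same trait at age 4. Because the cohort
data this design targets are not publicly deposited, the package ships a
synthetic-cohort generator with a paired ground-truth file, so every stage is
testable end to end and the statistical machinery can be validated by
parameter recovery.

## The growth model and the NWC

Each newborn contributes two observations: birthweight, treated as the
subject's curve observed at $t = 0$ (the population intercept of the curve is
essentially the mean birthweight, which makes this anchoring the natural
reading), and one weight measured at an irregular time $t \in (6.3, 96]$
hours. The model is a cubic fixed curve with a correlated random intercept
and slope per subject:

$$w_{ij} = \beta_0 + \beta_1 t_{ij} + \beta_2 t_{ij}^2 + \beta_3 t_{ij}^3
          + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij},$$

with $(b_{0i}, b_{1i}) \sim N(0, \Sigma_b)$ and
$\varepsilon_{ij} \sim N(0, \sigma^2)$. `fit_cubic_lmm()` estimates this by
maximum likelihood (not REML, so log-likelihoods remain comparable across
mean structures) through `lme4`, and predicts per-subject effects by
empirical-Bayes (BLUP) prediction. With only two observations per subject
the per-subject design is minimal, but the variance components are
identified across subjects because measurement times differ; the fit
therefore disables `lme4`'s per-subject observation-count check. A singular
random-effect covariance triggers a documented fall-back to a
random-intercept-only model (every $b_{1i}$ is then 0). Exactly polynomial
input (the noise-free degenerate case) bypasses the mixed model and returns
the exact least-squares cubic with zero variance components.

The population nadir is the root of
$\beta_1 + 2\beta_2 t + 3\beta_3 t^2 = 0$ in $(0, 96]$ with positive second
derivative, solved in closed form (`population_nadir()`); a cubic admits at
most one interior minimum, which the code asserts. The per-subject estimated
minimum weight is the subject curve evaluated at the population nadir, and

$$\mathrm{NWC}(\%) = \frac{\hat w_i(t_{\mathrm{nadir}}) - \mathrm{BW}_i}
                          {\mathrm{BW}_i} \times 100 .$$

A note on the published population curve: its coefficients
$(3241.442, -9.378, 0.119, -0.0004)$ place the interior minimum at 54.23 h,
while the accompanying analyses quote a nadir of 52.3 h. The two are
reconciled by coefficient rounding — the cubic term is printed to one
significant digit and the nadir location is sensitive to it. The package
always reports the nadir implied by its own fitted coefficients and never
hard-codes 52.3 h; the curve evaluated at 52.3 h still reproduces the
published mean NWC of −6.86% to within 0.01 percentage points, so nothing
downstream hinges on the discrepancy.

## Exclusion cascade

`apply_exclusion_cascade()` applies, in order: missing measurement time;
measurement after 96 h; hourly-rate outliers; incomplete key covariates.
Outliers are screened on the *hourly* change rate (percent of birthweight
per hour — the wording "per hour" makes rates, not total change, the
screened quantity; a flag restores the other reading) using Tukey fences at
$Q_1 - 3\,\mathrm{IQR}$ and $Q_3 + 3\,\mathrm{IQR}$ computed on the records
still in play after the first two stages. Published analyses report realized
fences of −0.50%/h (loss) and +0.19%/h (gain); these are that sample's
empirical fences, so the package computes its own by default and accepts
fixed fences via configuration. Each record carries exactly one exclusion
reason (the first triggered), and the cascade report conserves counts at
every stage.

## Clinical derivations

* **LDL-C** by the Friedewald equation, $\mathrm{TC} - \mathrm{HDL} -
  \mathrm{TG}/5$ (mg/dL), undefined above TG 400 mg/dL.
* **Blood pressure**: two readings differing by less than 5 mmHg are
  averaged; otherwise a third is required and the closest pair is averaged.
  A difference of exactly 5 mmHg (a case the stated protocol does not cover)
  is treated as requiring the third reading. When the third reading is
  equidistant from both others, the pair with the lower mean is taken — a
  deterministic, conservative tie-break, configurable via `tie =`.
* **z-scores**: plain $(x - \bar x)/s$ against age- (6-month bins) and
  sex-specific cohort cells (`build_reference()` / `zscore()`), with
  optional height-quantile bands for blood pressure so BP z-scores are
  independent of stature. No LMS (skewness-adjusted) scores; the targeted
  analyses use plain mean/SD standardization. Lookups never extrapolate: an
  unmatched cell returns `NA` with a warning.
* **High flags**: strictly above the empirical 90th percentile, using the
  linear-interpolation quantile definition (R type 7). External normative
  tables (e.g. pediatric BP references) can be supplied as a
  `cohort_reference` CSV; published "high BP" prevalences above 20% at age 7
  are only consistent with such an external threshold, so both routes are
  supported and neither is hard-wired.

## Path models and FIML

Each trait gets its own recursive path model (no cross-trait paths), in
three published variants plus a joint mediation form:
Model 1 at age 4 regresses the trait z-score on NWC, maternal education,
maternal pre-pregnancy BMI, gestational age and birthweight; Model 1 at
age 7 uses the same set minus gestational age (followed as printed — a
configuration flag can restore it); Model 2 at age 7 adds the same trait at
age 4 (the tracking edge, $\beta_5$). The joint variant stacks the age-4 and
Model-2 equations so the NWC effect decomposes into direct, indirect
(product of NWC→trait₄ and trait₄→trait₇) and total = direct + indirect —
an identity at the point estimates.

Estimation is full-information maximum likelihood written in the package:
rows are grouped by missingness pattern, each pattern contributes the
multivariate-normal log-likelihood of its observed marginal of the
model-implied moments (standard recursive-SEM algebra,
`implied_moments()`), and pattern-level sufficient statistics make the
evaluation cost independent of $n$. Exogenous means and covariance are
estimated jointly as auxiliary parameters (required for FIML when exogenous
values are missing), with the covariance log-Cholesky-parameterized and
residual variances log-parameterized so the optimizer (BFGS, relative
log-likelihood tolerance $10^{-12}$) is unconstrained. On complete data the
estimates coincide with per-equation least squares, the classical
equivalence for recursive systems, which the tests assert to $10^{-6}$.

The model $\chi^2$ is $2(\ell_{\mathrm{sat}} - \ell_{\mathrm{model}})$; the
saturated log-likelihood under missingness is obtained by an EM algorithm
for the unstructured multivariate normal, and the CFI/TLI baseline is the
independence model, whose FIML solution separates into per-variable
univariate ML fits. CFI, TLI and RMSEA use the standard formulas; a
saturated model (zero df) reports RMSEA 0 and an undefined (NA) TLI.
Confidence intervals are percentile bootstrap (not BCa — the plain
percentile method is the default reading of "bootstrapping"), resampling
children with replacement, refitting from the full-data solution, and
dropping failed replicates (more than 10% failures is an error);
with a fixed seed the intervals are bit-reproducible. Significance stars on
the correlation matrix follow the 0.05/0.01/0.001 convention with no
multiple-testing correction, matching the targeted analyses.

One design point deserves emphasis: the exact identity "total effect from
the joint model = NWC coefficient from the no-mediator model" holds only
when both equations condition on the same confounders. Because the printed
equations include gestational age at age 4 but not at age 7, the default
joint model inherits that asymmetry and the identity is only approximate;
`build_model(..., include_ga_age7 = TRUE)` gives the confounder-matched
model under which the tests verify the identity to $10^{-6}$.

## The synthetic cohort: what it emulates, and what it does not

`generate_newborns()` draws subject curves from the published fixed cubic
with bivariate-normal random effects and i.i.d. normal residuals, observes
them at $t = 0$ and at one time uniform on $(6.3, 96]$ h (only the range
6.3–96.0 h and mean 45.3 h of the real measurement times are reported;
uniform on that range, mean 51.2 h, is an acceptable stand-in and the
distribution is a configuration point). Variance components are not reported
for the real cohort, so the defaults — intercept SD 400 g, slope SD
1 g/h, correlation −0.2, residual SD 50 g — were fixed once as values a
perinatal researcher would call realistic for term newborns, chosen to give
an NWC spread near the reported SD of 2.32. The truth file stores each
subject's realized effects and the noise-free weight and NWC at the
subject's own curve minimum. Maternal education, pre-pregnancy BMI and
gestational age come from plausible normal distributions (no distributions
are published for them).

`generate_child_outcomes()` generates trait z-scores from exactly the
structural equations the path models estimate — confounders and NWC at age
4; those plus the tracking edge at age 7, with residual SD
$\sqrt{1-\beta_5^2}$ so z-scores stay near unit variance — with the
published tracking coefficients as defaults and NWC/confounder effects
defaulting to zero, the null structure the targeted analyses report.
Cross-trait residual correlations default to magnitudes in line with the
observed correlation structure (e.g. SBP–DBP 0.50). Natural-scale values
are reconstructed from published means/SDs; triglycerides are calibrated
from their median/IQR (IQR = 1.349 SD under normality). Raw components are
emitted so the derivation step has real work: TC/HDL/TG instead of LDL,
and two (or, when they disagree by ≥ 5 mmHg, three) BP readings around the
true pressure. `inject_missingness()` deletes values MCAR or MAR with the
rate depending on the tertile of an observed conditioning variable.

The generator does not emulate: hospital clustering or recruitment,
non-normal trait distributions (real triglycerides are right-skewed; the
generator's are normal on the z scale), measurement rounding beyond 1 g /
1 mmHg / 0.1 cm, age-dependent variance within a visit, or
missing-not-at-random mechanisms. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to real-data violations of it.

## Numerical choices and problem sizes

Defaults: bootstrap replicates 1000 (tests use the 200 minimum);
convergence tolerance $10^{-12}$ relative on the log-likelihood; nadir
grid oracle at 0.001 h resolution; BP rounding to integer mmHg. The test
suite validates parameter recovery at the study scale: 100 replicate
cohorts of 1500 newborns for the growth model (fixed effects recovered
within Monte-Carlo error of the generating values) and 200 replicate
cohorts of 312 children for the tracking coefficients, sizes chosen to
mirror the targeted study's analysis samples. Wald coverage of the null
NWC effect is checked over 200 replicates at $n = 150$ against the
[90%, 98%] band.

## Known limitations

* Two observations per subject identify the random-effect covariance only
  weakly at moderate $n$; occasional singular fits are expected and handled
  by the intercept-only fall-back.
* FIML assumes joint normality and missingness at random; neither is tested
  against alternatives.
* Bootstrap intervals are percentile-only; no BCa or studentized variants.
* No latent variables, categorical endogenous variables, or sandwich
  standard errors.
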