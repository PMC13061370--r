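---
title: "Methods: decomposing the ozone effect on term birth outcomes through gestational hypertension"
author: "ozmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing the ozone effect on term birth outcomes through gestational hypertension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ozmediate)
```

## The problem

Prenatal ozone exposure has been associated with term low birth weight
(term LBW: a live birth at 37–45 completed weeks weighing under 2500 g) and
term small-for-gestational-age (term SGA: weight below the 10th percentile
of a sex- and gestational-age-specific growth reference). One candidate
pathway runs through gestational hypertension: ozone raises the risk of
hypertensive disorders of pregnancy, which in turn restrict fetal growth.
`ozmediate` implements the full analysis chain needed to quantify how much
of the exposure effect is transmitted through that mediator in a registry
birth cohort: cohort construction, per-IQR effect estimation, composite
selection weighting, and two families of mediation decomposition, all
exercised end-to-end on a synthetic-cohort generator because the motivating
registry data (several million births from a Chinese provincial
birth-registry linkage, 2016–2022) are not publicly distributable.

Throughout, `A` is the whole-pregnancy mean ozone concentration (µg/m³),
`M` the binary gestational-hypertension flag, `Y` a rare binary outcome,
and `C` the adjustment set (maternal age, infant sex, pregnancy-mean
temperature, maternal occupation, gestational diabetes, husband's smoking).

## Models

Both working models are logistic:

$$\operatorname{logit} P(M = 1 \mid A, C) = \beta_0 + \beta_1 A + \beta_2^\top C$$
$$\operatorname{logit} P(Y = 1 \mid A, M, C) = \theta_0 + \theta_1 A + \theta_2 M + \theta_3 AM + \theta_4^\top C$$

with $\theta_3$ present only when an exposure–mediator interaction is
requested. Because the outcomes are rare (< 10% throughout), odds ratios
are read as risk ratios; every reported estimate records this labelling
(`or_as_rr`) along with the prevalence that licensed it. Effects are
expressed per interquartile-range (IQR) increase of exposure, comparing the
75th to the 25th percentile, with quantiles computed by linear
interpolation between order statistics (R type 7) so the scale is
reproducible.

## Counterfactual decomposition

`o3_mediate(..., variant = "counterfactual")` computes natural direct and
indirect effects on the odds-ratio scale. For an exposure contrast
$a^\* \to a$ it forms, for each subject's covariates $C_i$, the
counterfactual risk with the outcome model's mediator integrated against
the mediator model at the indicated exposure:

$$Q(a_y, a_m) = \frac{1}{n}\sum_i \sum_{m \in \{0,1\}}
  P(Y = 1 \mid a_y, m, C_i)\, P(M = m \mid a_m, C_i).$$

Averaging the risks first and forming odds ratios second yields marginal
("standardized") effects:

$$\mathrm{NDE} = \frac{\operatorname{odds} Q(a, a^\*)}{\operatorname{odds} Q(a^\*, a^\*)},\qquad
  \mathrm{NIE} = \frac{\operatorname{odds} Q(a, a)}{\operatorname{odds} Q(a, a^\*)},\qquad
  \mathrm{TE} = \mathrm{NDE} \times \mathrm{NIE},$$

so the product decomposition holds exactly as an identity of the estimator
(asserted to $10^{-12}$ relative in the tests). The proportion mediated is
$100 \cdot \log \mathrm{NIE} / \log \mathrm{TE}$, undefined when
$\mathrm{TE} = 1$ (a null contrast returns all ratios 1 and flags the
result). Empirical covariate averaging is the default; a fixed-covariate
(conditional) evaluation exists in the truth oracle for closed-form
cross-checks. An outcome prevalence at or above 10% does not abort the
fit but records a warning note on the result, since the OR-as-RR reading
degrades.

## Four-step decomposition

`variant = "four_step"` mirrors the traditional analysis: (1) a
total-effect model without the mediator, (2) the mediator model, (3) the
mediator-adjusted outcome model, and (4) a decomposition of the total
effect into the adjusted-model direct effect and the remainder. The total
effect in step 4 is computed by the same mediator-redistribution average
used above (predict with the mediator integrated to its
exposure-counterfactual distribution), the direct effect is
$\exp(\theta_1 \Delta)$ from the adjusted model, and the indirect effect is
their ratio, so TE = direct × indirect holds by construction. The Sobel
statistic
$z = \beta_1\theta_2 / \sqrt{\theta_2^2 \operatorname{var}\beta_1 + \beta_1^2 \operatorname{var}\theta_2}$
tests the product path. Because the literature is ambiguous about the
scale of the four-step mediation percentage, both readings are emitted:
`pm_pct` ($100\log \mathrm{IE}/\log \mathrm{TE}$) and `pm_excess_pct`
($100(\mathrm{TE} - \mathrm{DE})/(\mathrm{TE} - 1)$).

The redistribution TE and the step-1 per-IQR OR are different estimators
of the same quantity and agree only up to odds-ratio non-collapsibility,
which is of order the outcome prevalence: in the default regime
(prevalence 0.9%, mediator OR 6.5) the systematic gap is about $10^{-3}$
on the log scale, with per-replicate sampling noise of the same size at
$n = 10^5$. The consistency test therefore bounds the mean gap over five
replicates by $2\times10^{-3}$ rather than asserting a single-run
$10^{-3}$.

## Cox-framework variant

`variant = "cox"` rebuilds the decomposition with log-hazard coefficients
from a proportional-hazards outcome model fitted on the gestational-age
time scale (weeks; every subject fails or is censored at delivery; Efron
tie handling, since whole-week ages are heavily tied — Breslow is
switchable). Hazard ratios lack a risk-averaging analogue of $Q$, so the
covariate-conditional NDE/NIE expressions are averaged on the log scale
over the empirical covariate distribution. Under rarity the resulting
proportion mediated concords with the logistic variant (tested at
$n = 1.5\times10^5$).

## Bootstrap inference

Intervals are nonparametric bootstrap over subjects with bias-corrected
(BC, not BCa) percentile limits: the percentile bounds are shifted by
$2 z_0$ where $z_0 = \Phi^{-1}(\text{fraction of replicates below the
point estimate})$. Replicate $r$ draws its resample from child seed
stream $r$ of the root seed, so enlarging `n_boot` extends the replicate
set without reshuffling earlier draws; identical data and seed give
byte-identical intervals. Failed replicates are dropped and counted, and
more than 10% failures aborts. Bootstrap refits reuse the full-sample
coefficients as Newton warm starts with a step-based stopping rule
(relative step below $10^{-5}$; $10^{-9}$ for the cold point-estimate
fit), which leaves coefficient error orders of magnitude below resampling
noise.

## Weighting

Composite analysis weights multiply two pieces. Raking calibration
(classical iterative proportional fitting over category margins — the
standard survey-calibration algorithm; default margins are maternal age in
5-year bands, infant sex, and gestational age in completed weeks) aligns
the complete-record sample with eligible-population margins. Inverse
probability of selection weights are $1/\hat P(\text{included} \mid C)$
from a logistic selection model at eligibility level. The product is
truncated at the empirical 99th percentile and rescaled to mean 1. The
truncation cap is the upper order statistic at position
$\lceil 0.99\,n\rceil$ rather than an interpolated quantile: that choice
makes capping exactly idempotent (re-composing already-truncated weights
is a no-op), which an interpolated cap cannot guarantee when the extreme
weights are isolated.

## The synthetic-cohort generator

`sim_config()` encodes the study conditions the analysis assumes:

* exposure: truncated normal, mean 113.90, SD 13.03 µg/m³ on
  [62.35, 157.58] (the observed range), correlated 0.75 with
  pregnancy-mean temperature (°C, normal 14.58 ± 3.06);
* covariates: maternal age 30.0 ± 4.8 y truncated to [20, 45]; 47.6%
  female; occupation shares clerk/farmer/housewife/worker/other =
  0.166/0.330/0.110/0.065/0.329; gestational diabetes 10.3%; husband
  smoking 3.4%;
* mediator: logistic, prevalence target 103443/3394739 ≈ 3.05% (the
  computed ratio, not the rounded 3.1%), planted exposure effect OR 1.162
  per 19.93 µg/m³;
* outcome: logistic, prevalence target 30145/3394739 ≈ 0.89%, planted
  direct effect OR 1.034 per IQR, mediator effect OR 6.499, interaction 0
  by default — implying a total effect near 1.05 per IQR and a mediated
  proportion in the 35–40% range;
* auxiliary birth weight (3350 ± 420 g with small exposure and mediator
  shifts) and gestational age (39.0 ± 1.1 wk on [30, 45]) so the
  eligibility and outcome-derivation stages can be exercised; the binary
  analysis outcome is drawn from its own logistic model and is not forced
  to be consistent with the simulated birth weight — the two serve
  different test purposes;
* a logistic selection (inclusion) model for missingness mechanisms.

Model intercepts are calibrated numerically at configuration time so the
analytic prevalence (the average inverse-logit over a fixed internal
covariate draw of 20,000) equals the target. One root seed feeds
per-purpose child streams (covariates, exposure, mediator, outcome,
anthropometrics, selection, daily series), so enabling a later stage never
perturbs earlier draws and identical configurations reproduce byte-identical
cohorts. When a daily series is requested (seasonal sinusoid plus AR(1)
noise), it is shifted so each pregnancy mean reproduces the stored summary
exactly.

Ground truth for any configuration comes from
`true_mediation_effects()`: a Monte-Carlo oracle that draws covariates,
sets the exposure to each contrast arm, draws the mediator under the
indicated exposure (comonotone-coupled across arms through a shared
uniform, so null paths give NIE = 1 exactly), averages the exact model
outcome probabilities, and forms odds ratios, with delta-method Monte-Carlo
standard errors. A closed-form evaluation is available for the
no-interaction, fixed-covariate case and is cross-checked against the
oracle within 3 Monte-Carlo SEs.

What the generator does *not* emulate: spatial exposure structure and
geography, co-pollutant mixtures (beyond the temperature correlation),
model misspecification (both generative models are exactly logistic, so
parameter recovery is well-posed), and real growth-standard percentiles
(`make_growth_reference()` is a synthetic, monotone stand-in; a real
reference table can be supplied as three-column text). Passing tests
therefore demonstrate correctness of the estimators under the assumed
statistical structure, not robustness to violations of it.

## Simulation scenarios behind the validation studies

These problem sizes are the package's chosen test conditions.

* **Parameter recovery** — 100 cohorts of n = 50,000, outcome prevalence
  1%, planted proportion mediated 20%. The planted total effect is 1.5
  per IQR contrast: at the motivating study's effect size (TE ≈ 1.05) and
  this n, $\log TE$ crosses zero with non-negligible probability and the
  proportion mediated has no finite moments, so a mean-recovery criterion
  is only meaningful with an identifiable total effect. The mediator
  slope (0.03793 per µg/m³) was solved iteratively against a
  high-precision Monte-Carlo truth read so the planted proportion mediated
  lands at 20%.
* **Bootstrap coverage** — 200 cohorts of n = 20,000 with 200 BC
  replicates each, same planted effects but null covariate slopes and a
  crude exposure-only analysis model (exactly specified), keeping 40,000
  bootstrap refits inside a few minutes of CPU.
* **Selection-bias reduction** — 50 cohorts of n = 60,000, outcome
  prevalence 10%, temperature driving selection (logit slope −0.5/°C) and
  the outcome (+0.25/°C log-odds) while correlating 0.75 with exposure;
  the unadjusted complete-case estimate is then biased for the
  full-cohort association and IPS weighting removes most of that bias.
  Selection is kept moderate deliberately: under strong selection the
  99th-percentile weight cap itself becomes a bias source and the
  comparison stops isolating what it is meant to show.

## Numerical choices and degenerate inputs

* Logistic fits go through `stats::glm` (IRLS) with deviance tolerance
  $10^{-12}$, tight enough to reproduce closed-form 2×2 odds ratios to
  $10^{-8}$; non-convergence and complete separation are explicit errors.
* Eligibility rules claim records in a fixed documented order (first
  failing rule wins), so flowchart arithmetic is exactly reproducible; a
  record that a rule cannot evaluate is excluded under `unparseable`,
  never dropped silently. The birth-weight plausibility window defaults
  to 500–6000 g (configurable; the motivating analysis does not define
  "implausible").
* SGA lookup uses completed weeks (floor), matching the term definition
  of 37–45 completed weeks; a missing (week, sex) reference row yields a
  missing SGA flag, which is a value, not an error.
* Exposure windows use the closed [LMP, delivery] interval and require
  ≥ 80% daily coverage (configurable) before a mean is reported.
* A constant mediator, an all-zero weight vector, an empty eligible set,
  or a degenerate counterfactual risk (0 or 1) each raise a targeted
  error naming the problem.

## Limitations

Single binary mediator only; no mediator–outcome confounder sensitivity
analysis (e.g. E-values); no trimester-specific exposure windows; the
weighted fits use pseudo-likelihood with sandwich variances rather than a
full design-based framework; and the OR-scale decomposition leans on the
rare-outcome approximation, so results for common outcomes should be read
as odds ratios, as flagged in the output metadata.
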