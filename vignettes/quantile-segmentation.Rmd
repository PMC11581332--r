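---
title: "Quantile-based segmentation of HRQoL in multiple sclerosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-based segmentation of HRQoL in multiple sclerosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qolseg)
library(dplyr)
```

## The problem

Generic health-related quality of life (HRQoL) instruments such as the
EQ-5D and the visual analogue scale (VAS) are normed for the general
population. For people living with a chronic disease like multiple
sclerosis (MS), a raw score is hard to act on: HRQoL declines with age and
with time lived with the disease, so "low" should mean *low relative to
peers of the same age and disease duration*, not low relative to the
healthy population. `qolseg` implements a segmentation that makes exactly
this comparison, together with the downstream models used to ask *which
disease characteristics and symptoms accompany unexpectedly low HRQoL*.

## The segmentation model

For an HRQoL outcome $y$ (EQ-5D index or VAS, both on a 0–100 scale) and
covariates $x = (\text{age}, \text{years since diagnosis})$, we estimate
three conditional quantile surfaces by linear quantile regression,

$$\hat q_\tau(x) = x^\top \hat\beta_\tau, \qquad
  \hat\beta_\tau = \arg\min_\beta \sum_i \rho_\tau(y_i - x_i^\top\beta),
  \qquad \tau \in \{0.25, 0.5, 0.75\},$$

where $\rho_\tau(u) = u(\tau - \mathbf 1\{u<0\})$ is the pinball (check)
loss. A participant is classified **low** if their measurement falls
*strictly below* the fitted 25th-percentile surface at their own age and
disease duration, **high** if *strictly above* the 75th, and **normal**
otherwise. Ties at either boundary go to the normal range; this strict
reading matters for the EQ-5D, which has a ceiling mass at 100 that can
sit exactly on a fitted surface. Four quartile bins (below q25; [q25,
q50); [q50, q75]; above q75) refine the three groups so that bin 1
coincides with "low" and bin 4 with "high".

Because the adjustment covariates absorb the age and duration gradients,
the resulting groups are near-balanced on both by construction, and any
remaining group contrasts (symptoms, disability, treatments, benefits)
are interpretable free of those two confounders.

**Discordance.** The same bins compare the two instruments per person:
with EQ-5D in the top quartile and VAS in the bottom two (or EQ-5D in the
top two and VAS in the bottom one), the person rates their overall health
markedly *worse* than their five-domain profile suggests (`lower_vas`);
the mirror image is `higher_vas`. Of the 16 bin pairs, exactly 3 map to
each discordant direction.

### Solving the quantile regressions

No quantile-regression solver is part of the package's dependency stack,
and the fitted surfaces are the core of the method, so the linear program
is solved in-package by a Frisch–Newton primal–dual interior-point method
on the bounded-variable dual
$\max\{y^\top a : X^\top a = \tau X^\top \mathbf 1,\ a \in [0,1]^n\}$,
with Mehrotra predictor–corrector steps. Interior-point iterates approach
the optimal face from inside, so a final *vertex polish* solves the
$p \times p$ system through the $p$ observations with the smallest
absolute residuals and keeps that basic solution when it does not
increase the loss; on continuous data this recovers the exact LP vertex.
The test suite checks the solver against an independent brute-force
oracle (enumerating all interpolating $p$-subsets) to $10^{-9}$ on
hundreds of small random instances, and checks the textbook on-sample
property $\tau - p/n \le \#\{y_i < \hat q_\tau(x_i)\}/n \le \tau$ on
continuous cohorts.

Numerical choices: columns and outcome are rescaled to unit max before
iterating; the Newton system falls back to progressively ridged solves if
ill-conditioned; iterations stop at a duality gap below $10^{-10} n$.
Quantiles are fitted independently per $\tau$ (as the primary analysis
prescribes); crossing of fitted surfaces is detected, reported in a
crossing table, and repaired pointwise by sorting the three fitted values
before classification. Degenerate designs (collinear columns) are
refused with the offending columns named.

## Scoring

**EQ-5D index.** A value set (tariff) maps the five ordinal domain levels
to a utility $U = c - \sum_d \delta_{d,\ell_d}$; the package rescales
$[U_{\min}, 1]$ linearly to $[0, 100]$, so full health scores 100 and the
tariff's worst profile 0. Whether the published 0–100 index is exactly
this linear rescale is not fixed by convention; it is this package's
documented choice. Published country tariffs are licensed tables that the
user supplies as a CSV + JSON pair; the packaged tariff
(`toy_value_set()`) is synthetic, clearly labelled, and used only in
tests and examples.

**MS Severity Score.** `compute_msss()` rank-normalizes EDSS within
integer-year disease-duration strata: with mid-ranks $r_i$ (ties share
the mean rank) in a stratum of size $n_s$, the score is
$10\, r_i/(n_s+1) \in (0, 10)$ — the speed of disability accumulation
relative to peers with equal disease duration. Sparse strata are pooled
symmetrically outward ($d \pm 1, d \pm 2, \dots$) until a minimum stratum
size (default 5) is reached; the normalization and the pooling rule are
isolated behind parameters so a published lookup-table variant could be
added. The score is kept out of automated model building and enters only
the dedicated subsample re-fit (`refit_with_msss()`), because it is
observed for roughly 55% of participants.

## Association models

Group membership (low / normal / high, reference: normal) is modelled by
a baseline-category multinomial logit fitted by full Newton–Raphson with
step halving; convergence requires every score component below
$10^{-8}$, and coefficients are reported as relative risk ratios (RRR)
with Wald 95% intervals from the observed information. Wald rather than
profile intervals is deliberate: it matches the RRR [95% CI] presentation
convention of registry analyses. A coefficient-magnitude cap (15 on the
log scale) triggers a separation warning naming the covariate — sparse
cells (rare comorbidities, near-empty category combinations) do separate
in registry data, and silently exploding estimates are worse than a loud
warning.

**Forward retention.** Pre-specified confounders (sex, clinical
phenotype, gait-impairment class) are always kept. Candidates are offered
*one at a time in a fixed documented order* (symptoms first, then symptom
burden, benefits/employment, BMI, sociodemographics, treatments,
first-symptom history, familial risk, comorbidities) and retained iff
they lower the AIC by at least 2 points — a drop of exactly 2.0 is
retained. Forward selection is order-dependent and no canonical order
exists, so the order is a configuration input with this default; the
`SelectionTrace` records every step (AIC before/after, decision, reason)
so the path is auditable. Collinearity of the final design is summarized
by generalized variance-inflation factors (determinant-ratio definition,
categorical terms aggregated), flagging $\mathrm{GVIF}^{1/(2\,df)} >
\sqrt 5$.

## Sensitivity analysis: simultaneous quantile regression

Categorizing HRQoL loses information. The sensitivity analysis therefore
re-asks the association question on the *continuous* outcomes: all three
quartile levels are fitted on a design in which age and disease duration
enter as restricted cubic splines (default 3 knots at the 10th/50th/90th
percentiles — the spline family and knot count are configurable since
only "splines" is prescribed), plus the same confounders and candidates.
Inference is by a participant-level bootstrap (default $B = 100$): each
resample re-fits *all* taus, giving a joint covariance across every
coefficient of every tau, hence valid cross-tau contrasts (is a covariate
reshaping the lower tail specifically?). P-values are two-sided normal
approximations on bootstrap SEs. Resamples that lose a category or
otherwise degenerate the design are redrawn (at most 10 times, counted
and reported). Candidate retention uses "p < 0.05 at any fitted tau";
the alternative readings (a specific tau, or a joint test) are not
prescribed anywhere, and the any-tau rule is the most inclusive, which is
the conservative direction for a screening step. `select_by_pvalue()`
applies this rule to a given fit, matching its declared signature.

## The synthetic cohort generator

The registry data behind the published analysis are not public, so the
package ships a seeded generator whose defaults encode the published
cross-section as its study conditions; the defaults are also shipped as
`inst/extdata/smsr_like.yaml`. What it emulates, and how:

* **Age**: truncated normal on [18, 90], location 48.35 and scale 15.21
  solved (one-time, weighted least squares on the three printed
  quantiles) so the median/IQR reproduce 49 [38; 58].
* **Disease duration**: gamma (shape 1.047, scale 18.91) *calibrated
  after truncation* at age − 16 (diagnosis in adulthood), matching the
  printed 9 [4; 17]; calibrating the untruncated gamma instead would
  undershoot the quantiles by roughly two years.
* **Latent severity** $S$: linear in duration and phenotype plus standard
  noise; it drives the twelve symptom flags (logistic models whose
  intercepts are root-solved against the realized $S$ so each prevalence
  hits its target), the SRDSS gait-impairment class (thresholds at the
  realized quantiles), EDSS (monotone half-point map), disability
  benefits, employment and treatment class (sequential logits with
  severity slopes, intercepts again solved against realized marginals).
* **The HRQoL pair**: a shared covariate predictor (severity, selected
  symptoms, benefit receipt, age) plus bivariate standard residuals with
  correlation `residual_rho` gives latents $(E^*, V^*)$; each is mapped
  by a monotone rank-quantile transform onto its target marginal — a
  piecewise-linear quantile function interpolating the printed
  full-sample and per-group quantiles — with upper censoring of the EQ-5D
  at 100 (ceiling mass 0.135, set so the classified top-quartile group
  has median exactly 100) and integer rounding of the VAS.
  `residual_rho = 0.55` was fixed once by grid search so the total
  Spearman correlation of the two instruments is ≈ 0.74; the split
  between shared-covariate dependence and residual dependence is a
  modelling choice, as only the total is published.
* **Missingness**: the five categorical variables and BMI are masked
  independently at rates below 3%; EDSS/MSSS are observed with
  probability 937/1697. Age, duration and HRQoL are never masked — they
  are inclusion criteria.

Every quantity used in generation (effects, solved intercepts,
thresholds, per-participant latents, seed) is recorded in a
`TruthRecord` for recovery testing, and identical (configuration, seed)
pairs reproduce byte-identical tables.

**What the generator does not emulate.** Covariate *joint* structure
beyond the single severity latent (the publication reports only
marginals); longitudinal trajectories (one measurement per participant);
item-level EQ-5D profiles (the index is generated directly, since the
real tariff is not public); informative missingness. Consequently,
passing calibration tests shows that the pipeline reproduces the printed
cohort-level statistics under a faithful stand-in — it cannot certify
behaviour on the real registry's unpublished joint distribution, and the
published regression coefficient tables are deliberately out of scope.

## Problem sizes and runtime choices

Defaults mirror the study conditions: cohorts of n = 1697, three taus,
B = 100 bootstrap replicates. The test suite exercises reduced sizes
where the property under test does not need the full size (e.g. B = 8–60,
n = 400–2000 for bootstrap-shrinkage and power properties; n = 5000 with
100 replicates for Wald coverage), chosen so each property is measured
with adequate Monte-Carlo precision. Monte-Carlo tests draw all
replicates from one master RNG stream.

## Known limitations

* The AIC forward path is order-dependent by construction; the trace
  makes the path transparent but does not remove the dependence.
* Bootstrap SEs for extreme quantiles of heavily tied outcomes (VAS on
  the integer grid, EQ-5D at the ceiling) inherit the usual
  quantile-estimation granularity; the generator reproduces these ties
  deliberately.
* The segmentation treats the three taus independently; crossing is
  repaired, not prevented. Crossing-constrained joint estimation is a
  non-goal for the primary classification.
* BMI imputation is a deterministic single regression fill-in, not
  multiple imputation; imputed rows are flagged.
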