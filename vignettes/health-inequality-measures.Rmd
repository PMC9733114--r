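---
title: "Measuring health inequality from complex household surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health inequality from complex household surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthineq)
```

## The measurement problem

Equity monitoring asks how a binary health indicator — here, whether a
pregnant woman slept under an insecticide-treated net (ITN) — differs
across population subgroups defined by *equity stratifiers*: wealth
quintile, education, urban/rural residence, sub-national region. The
inputs are estimates from complex household surveys such as UNICEF's
MICS, which use multistage stratified cluster sampling, so both the
subgroup estimation and the inequality summaries must respect the
design.

`healthineq` implements the whole chain: design-based subgroup
prevalence estimation from individual records, the four standard summary
measures of inequality with uncertainty intervals (UIs), a survey
simulator with known truth for validation, and a packaged reproduction
of a published two-survey Ghana analysis.

## The four summary measures

Let $y_j$ be the prevalence (percent) in subgroup $j$ and $\mu$ the
overall weighted prevalence of the setting. With a *favourable*
indicator (higher is better):

* **Difference** $D = y_{\text{advantaged}} - y_{\text{disadvantaged}}$
  (percentage points; simple, absolute). For *ordered* dimensions the
  extremes are fixed by the declared ranking — richest vs poorest
  quintile, secondary+ vs no education, urban vs rural — regardless of
  which performs better, so $D$ can be negative (it is, throughout the
  Ghana tables: the disadvantaged groups use ITNs more). For
  *non-ordered* dimensions (region) the extremes are data-driven,
  $D = y_{\max} - y_{\min} \ge 0$.
* **Ratio** $R = y_{\text{advantaged}} / y_{\text{disadvantaged}}$
  (simple, relative), same extreme-selection rules; $R = 1$ means no
  inequality.
* **Population Attributable Risk**
  $\mathrm{PAR} = y_{\mathrm{ref}} - \mu$ (complex, absolute): the
  population-level gain if everyone attained the reference subgroup's
  level. Because $\mu$ is population-weighted, PAR accounts for subgroup
  sizes.
* **Population Attributable Fraction**
  $\mathrm{PAF} = 100 \cdot \mathrm{PAR} / \mu$ (complex, relative).
  The identity holds exactly, pre-rounding, for every computed pair —
  point estimates and interval bounds alike — and is enforced by tests.

### Reference-group rules

For ordered and binary dimensions $y_{\mathrm{ref}}$ is the
most-advantaged subgroup. For non-ordered dimensions with a favourable
indicator we take the **best-performing** (highest-estimate) subgroup.
Narrative descriptions of this family of measures sometimes phrase the
regional reference as "the region with the lowest estimate"; the
published point estimates this package reproduces (regional PAR
$29.7 = 62.3 - 32.6$ in 2011 and $25.8 = 75.5 - 49.7$ in 2017) are
arithmetic only under the best-performing rule, which also matches PAR's
interpretation as an attainable gain, so that is the rule implemented.
An adverse-indicator mode (`favourable = FALSE`) mirrors every rule.

### Truncation and the zero rows

A PAR pointing the "wrong" way — reference below the average for a
favourable indicator — is truncated to zero: there is no attributable
population gain, hence no inequality in this sense. Published tables
print such cells as `0` with symmetric bounds (e.g. $0 \pm 6.4$), so the
UI is centred on the reported (truncated) point estimate with the
untruncated standard error; `truncate_par = FALSE` recovers the raw
value. Truncation reproduces every zero row of the Ghana table for all
ordered dimensions in both years.

### Uncertainty intervals

The published analysis reports 95% UIs without stating their
construction. Two constructions are provided and cross-checked:

* **Delta method** (default): $se_D = \sqrt{se_1^2 + se_2^2}$ with a
  normal interval; $R$ on the log scale with
  $se_{\log R} = \sqrt{(se_1/y_1)^2 + (se_2/y_2)^2}$, back-transformed;
  $se_{\mathrm{PAR}} = \sqrt{se_{\mathrm{ref}}^2 + se_\mu^2}$, with the
  covariance between $y_{\mathrm{ref}}$ and $\mu$ set to zero — an
  approximation, since the reference subgroup is part of the overall
  mean; the PAF interval is the PAR interval rescaled by $100/\mu$.
* **Cluster bootstrap** (`ui_method = "bootstrap"`): PSUs resampled with
  replacement within strata, all measures recomputed per resample
  (extremes re-selected for non-ordered dimensions), percentile
  intervals. This route is covariance-honest and is the package's own
  check on the delta approximation: on a 2-stratum, 30-PSU synthetic
  design, the two interval constructions for $D$ agree within 15% of the
  half-width, and the Taylor standard error matches a 2000-replicate
  bootstrap within 10%.

When a table carries confidence bounds but no standard errors (the usual
published format), `health_inequality()` recovers approximate SEs by
inverting the logit-interval construction (`se_from_ci()`).

## Design-based estimation

Subgroup prevalence is the ratio estimator
$100\sum w_i y_i / \sum w_i$. Its variance uses stratified between-PSU
Taylor linearization under the with-replacement approximation — the
standard estimator for MICS/DHS-type designs — with no finite-population
correction and normal (not $t$) critical values; both choices are
approximations appropriate for designs with many PSUs and small
sampling fractions, and both are documented rather than hidden. Domain
(subgroup) estimation keeps every PSU in the variance formula with a
zero contribution outside the domain. Strata with a single PSU follow a
declared policy: `certainty` (zero variance, warn — the default, so
small simulated designs stay runnable), `collapse`, or `error`.

Confidence intervals for prevalences use the logit transform: a normal
interval on $\mathrm{logit}(p)$ with the delta-method SE,
back-transformed. This keeps intervals inside $(0, 100)$ and asymmetric
about the estimate — matching the shape of published survey intervals —
and collapses gracefully as $se \to 0$. Boundary estimates (0 or 100%)
fall back to the exact one-sided Clopper–Pearson bound, which needs the
unweighted $n$. Records with a missing stratifier value stay in the
overall average $\mu$ (a setting-level quantity) and drop out of that
dimension's disaggregation only.

## What the simulator emulates

`population_config()` / `build_frame()` / `draw_sample()` generate
MICS-like data with known truth:

* **Design**: regions split into urban and rural strata; census
  enumeration areas (EAs) as clusters with log-normally dispersed
  household counts; stage 1 selects EAs systematically with probability
  proportional to size (randomized list order — field frames are orders
  of magnitude larger than simulated ones, so a fresh random ordering
  per draw restores the rich sample support that systematic selection
  has in practice; units whose inclusion probability reaches 1 become
  certainty selections); stage 2 is an equal-probability household
  sample within each EA. Weights are inverse inclusion-probability
  products, so a census take yields weights of exactly 1.
* **Outcome model**: per-region log-odds intercepts plus additive
  effects for residence, latent wealth quintile and education, plus an
  EA-level normal random intercept whose variance is mapped from the
  target intra-cluster correlation by the latent-logistic
  approximation $\sigma_u^2 = \mathrm{icc} \cdot (\pi^2/3) /
  (1 - \mathrm{icc})$.
* **Wealth index**: binary asset indicators loaded on a latent wealth
  score (which also has an EA-level component, so assets cluster
  geographically, and an urban premium); the analysis index is the
  first principal component of the standardized asset matrix,
  sign-aligned so more assets means a higher score, cut at weighted
  20/40/60/80 percentiles. By default the index is computed once from
  the full frame and carried as a household attribute, which keeps
  subgroup membership a fixed population quantity — so design-based
  recovery checks and the census identity are exact;
  `draw_sample(..., wealth = "sample")` recomputes it survey-style from
  the sampled households instead.
* **Eligibility**: each household contains an eligible (pregnant) woman
  with a configurable probability; only eligible women become analysis
  records, which reproduces the small per-subgroup counts typical of
  pregnancy indicators.

Outcomes are realized once, at frame construction. `true_summaries()`
therefore offers two truths: `"expected"` (EA intercept integrated out
of the model, probabilities averaged over the frame) and `"realized"`
(the frame's actual outcomes — the finite-population estimand of
design-based theory). A census run of the estimation pipeline equals the
realized truth *exactly*, a noise-free end-to-end identity that the
acceptance tests assert to the last bit.

### The default scenario and its calibration

`default_ghana_config()` ships a ten-region population whose frame sizes
follow 2010 census population shares, with effect sizes read off the
published 2017 gradients (urban $-0.6$ log-odds; wealth $-0.3$ per
quintile step; education $-0.15$ per level) and region intercepts
calibrated by a short fixed-point iteration so the marginal regional
prevalences approximate the published 2017 column. The default draw — 3
EAs per stratum, 31 households per EA, eligibility 0.5 — yields roughly
900 respondents, matching the published survey's pregnant-women sample,
with small regions oversampled relative to population as in MICS.

### What the validation shows — and does not

The packaged checks run at these problem sizes: 500 sampling replicates
of the ~900-respondent default design for parameter recovery (subgroup
means within 3 Monte-Carlo SEs of the realized frame truth; 95% UI
coverage for $D$ within 92–98% on the ordered/binary dimensions), 500
replicates at ~180 respondents per subgroup for logit-CI coverage
(93–97%), and a 30-PSU design against a 2000-replicate bootstrap oracle.
Coverage is asserted for $D$ on ordered/binary dimensions only, where
$D$ is a fixed contrast; for non-ordered dimensions $D$ is a range
statistic ($y_{\max} - y_{\min}$) whose extreme-selection step biases it
upward in small samples — a known property of data-driven extremes, not
a defect of the interval.

The generator emulates design features, not field reality: there is no
nonresponse, no weight calibration or poststratification, no
finite-population correction, eligibility is independent of the outcome,
and the intra-cluster correlation is a free parameter rather than a
claim about any country. Passing these checks shows the estimators are
correct under the stated design; it does not certify behaviour under
violations the generator does not model.

## Numerical conventions

* Estimates ride the 0–100 percent scale end to end; proportions appear
  only inside variance formulas. This makes comparisons with published
  tables literal.
* Reporting rounds half away from zero at one decimal
  (`round_report()`), the convention of the published tables; base R's
  half-to-even rounding would disagree on exact halves.
* Ties for a non-ordered extreme are broken by label sort order, with a
  warning.
* Zero-width intervals (all SEs zero) are legal and collapse to the
  point estimate; a zero denominator makes $R$ an error rather than an
  infinity.
* CSV interchange is comma-separated UTF-8 with `.` decimals and empty
  cells (never sentinel numbers) for missing optional values; every
  malformed cell is reported with its row and column, never silently
  dropped.

## Reproducing the published Ghana analysis

`reproduce_tables()` recomputes all 32 printed point estimates (4
dimensions × 4 measures × 2 survey years) from the packaged subgroup
table, using the published overall prevalences (32.6% in 2011, 49.7% in
2017) as $\mu$ — the microdata behind them are out of scope, so the
complex measures are computed from in-table numbers alone. Thirty of 32
cells match at one-decimal rounding; the two exceptions (regional PAF
2011, printed 91.3 vs 91.1 recomputed; residence $D$ 2017, printed
−26.1 vs −26.0) are consistent with the original analysis having worked
from unrounded internals, and are flagged with explanatory notes rather
than failed, so genuine regressions still surface.

```{r reproduce}
rep <- reproduce_tables()
attr(rep, "n_match")
```

## Limitations

Beyond the generator simplifications above: the delta-method PAR
variance ignores the reference–mean covariance (use the bootstrap when
records are available); published-table workflows inherit whatever
interval construction the source used, recovered only approximately by
`se_from_ci()`; and two-survey change is read informally through UI
overlap (`ui_overlap()`) — no formal trend test is provided.
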