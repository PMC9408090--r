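---
title: "Costing health-related productivity loss in FIFO workforces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing health-related productivity loss in FIFO workforces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpaicost)
```

`wpaicost` estimates what health conditions and lifestyle risks cost a
workforce in lost productivity. This vignette explains the model it
implements, the choices made where the methodology is genuinely open, and
what the synthetic-data tests do and do not establish.

## The measurement model

### Risk classification

Eight conditions are classified high/low risk per worker from standard
screening instruments. The thresholds live in `risk_rules()` and each can
be overridden:

| condition | instrument | high risk when | default |
|---|---|---|---|
| psychological distress | K10 (10–50) | score ≥ cut | 22 |
| poor physical health | SF-8 PCS (0–100) | score < cut | 50 |
| poor sleep | duration + quality | hours < cut and/or quality in worst two levels | 7 h |
| risky alcohol | AUDIT-C (0–12) | score ≥ sex-specific cut | 4 (men), 3 (women) |
| smoking | status | currently smoking | — |
| insufficient activity | IPAQ MET-min/week | minutes < cut | 600 |
| weight problem | BMI kg/m² | outside healthy band | [18.5, 25) |
| poor diet | serves/day | fruit < cut and/or veg < cut | 2 and 5 |

Two boundary conventions deserve note. BMI bands are printed in screening
tables as 18.5–24.9 versus 25–29.9/≥30, which leaves [24.9, 25) formally
unassigned; we use the half-open healthy band [18.5, 25), which is
exhaustive and matches the printed categories. For physical health the
published low-risk criterion is a verbatim repeat of the high-risk one (an
apparent typo); we follow the prose definition: high risk iff PCS < 50.

Counts of co-occurring conditions are tiered low (0–2), medium (3–4) and
high (5+); `risk_tier()` is total and non-overlapping over counts 0–8.

Classification is complete-case: a worker missing any needed instrument
response is flagged `incomplete`, excluded from analysis and counted in
the run manifest — mirroring how survey studies drop insufficient
responses. A missing item that cannot alter a disjunctive rule (missing
fruit serves when vegetables are already below their minimum) still yields
a definite flag, per ordinary three-valued logic.

### WPAI-GH scoring under a 4-week recall

The WPAI-GH items are defined over 7 days; administered with a 4-week
recall (to smooth over compressed FIFO rosters), reported hours are
divided by 4 (`rescale_recall()`). With `m` missed hours/week, `w` worked
hours/week and impairment rating `r` (integer 0–10):

- absenteeism `a = m/(m + w)`;
- presenteeism `p = r/10`;
- total loss `t = a + (1 − a)·p`.

All are carried internally as fractions and reported as percentages, so
`t` is guaranteed to lie between `max(a, p)` and `min(a + p, 1)`. Workers
with `m = w = 0` (not at work in the window) have no defined loss; they
are excluded with a logged count rather than scored as zero.

One scale ambiguity is worth recording: published per-week presenteeism
summaries from 4-week administrations are sometimes consistent with the
0–10 rating itself having been divided by 4 along with the hours items.
The rating is a point-in-time impairment judgement, not a time-aggregated
quantity, so this package applies the recall division to hours only (the
absenteeism ratio is invariant to it) and keeps `p = r/10`. Comparisons
with per-week published means should keep that factor of 4 in mind;
group *differences*, rank tests and regression structure are unaffected.

### Costing

Costing is human-capital: lost time is valued at the gross wage.
`salary_model()` defaults to AUD 134,323.20/year (average weekly mining
earnings × 48 working weeks, i.e. 52 minus 4 weeks of leave). Two
pathways are deliberately kept distinct and labelled:

- **Unadjusted, per worker** (`excess_cost_table()`): the raw high–low
  group difference in mean loss (`excess_loss()`), valued as
  `excess/100 × salary`, with a Mann–Whitney test per cell.
- **Adjusted, per 1000 workers** (`adjusted_cost_table()`): the
  condition's coefficient from an OLS regression of loss on age, gender,
  FIFO role (7 levels, management reference), shift pattern, shift hours,
  consecutive days at work and at home, years in FIFO, all eight
  condition flags and the multiple-risk tier; valued as
  `prev/100 × β/100 × salary × 1000`.

A condition with a negative adjusted coefficient shows no excess loss for
that measure: its cost is recorded as not applicable, it contributes
nothing to totals, and it is dropped from the mean's denominator
(`aggregate_costs()`).

The regression enters the tier dummies *alongside* the eight flags
because that is how the adjusted model is specified in applied practice;
the tier is a step function of the flag count, so this induces
collinearity by design, which the VIF output surfaces rather than hides.
Whether alcohol should enter as the binary flag or the raw AUDIT-C score
is not settled in the field; the flag is used, consistent with the other
seven conditions.

### Inference

- `mann_whitney()`: tie-corrected normal approximation, two-sided; the
  sign convention reports `z < 0` when the high-risk group is
  stochastically larger, matching applied costing tables. At very small
  n the normal approximation deviates from the exact permutation
  distribution; the tests therefore verify the U statistic exactly
  against a pair-counting oracle and the p-value's ordering against an
  exhaustive-permutation oracle.
- `kruskal_wallis()`: tie-corrected H with a χ² reference (wrapping
  `stats::kruskal.test`); `dunn_bonferroni()`: pairwise mean-rank z tests
  with the tie-corrected pooled variance, p multiplied by k(k−1)/2 and
  capped at 1.
- `fit_two_part()`: logistic regression for any loss on the full sample,
  OLS on the positive subsample, Wald (not profile) confidence intervals
  — fast, standard in applied cost studies, and their ~95% coverage is
  itself verified by a 500-seed null simulation in the test suite. An
  optional `log` transform is available for the positive part; the
  default is the raw percentage scale, since no transform is standard.
  Possible separation is flagged with a warning, not an error.
- `vif()`: the per-column definition 1/(1 − R²ⱼ); rank-deficient columns
  report `Inf`. `fit_adjusted_excess()` refuses rank-deficient designs,
  naming the aliased terms.

### Probabilistic sensitivity analysis

`run_psa()` redraws each adjusted excess from `normal(point, SE)` and
each prevalence from a beta distribution matched to its point estimate
and SE (conventional health-economics practice when only point estimates
and SEs are reported), holding the salary fixed, and recomputes the
per-1000 costs for `n_sims` draws (default 1000, the conventional size at
which mean parameters converge). Summaries are percentile 2.5/97.5
certainty intervals. The contributing-condition set is frozen at the
point-estimate sign, and negative draws are retained by default so the
Monte-Carlo mean stays unbiased; `clamp_negative = TRUE` is available and
documented as upward-biasing. Zero SEs yield exactly degenerate draws.

## The synthetic cohort generator

`generate_cohort()` exists so that every downstream stage is testable
with no external data. It emulates, by design:

- **Correlated risk flags** from a latent-Gaussian equicorrelation copula
  (default pairwise latent correlation 0.2 — condition co-occurrence is
  reported in workforce surveys but no correlation structure is, so a
  single modest exchangeable value is the defensible default). Marginal
  flag probabilities equal the configured prevalences *exactly* by
  construction (threshold on a unit-variance latent).
- **Instrument responses generated backwards from the intended flag**
  (e.g. K10 drawn from 22–50 when flagged, 10–21 otherwise), with a small
  margin around every threshold so floating-point boundaries cannot flip
  a classification. This makes "classifier output = generator intent for
  100% of workers" a meaningful end-to-end test.
- **Zero-inflated losses** from a hurdle: any-loss is Bernoulli with
  log-odds linear in the flags; the intercepts are calibrated
  analytically (integrating the hurdle probability over the copula's
  shared factor, then root-finding) so the marginal any-absenteeism and
  any-presenteeism probabilities equal the surveyed 20.4% and 53.7%
  under the default prevalences and effect sizes.
- **Positive losses**: missed hours from a lognormal with mean 16 and sd
  20 per 4 weeks, truncated to [1, contract hours] (right-skewed and
  bounded, matching the surveyed 16.07 ± 20.34, range 1–96); scheduled
  hours default to shift hours × days on × 28/(days on + days off), about
  192 h/4 weeks for a 12-h 8-on/6-off roster. The impairment rating is a
  latent normal (base 1.8, sd 1.5) plus condition increments, rounded and
  clamped to 1–10 — reproducing a discrete, right-skewed rating
  distribution.
- **Default effect sizes** giving the largest hurdle effects to poor
  physical health, insufficient activity (absenteeism) and psychological
  distress (presenteeism), mirroring the ordering reported for FIFO
  workforces; effects are specified separately for each hurdle and each
  positive part because the two outcomes behave differently in two-part
  analyses.
- **Demographics** sampled independently from workforce margins (66%
  male, mean age ~40, 57% rotation shifts, typical 8-on/6-off to
  14-on/7-off rosters); no demographic–risk correlation by default.

What it does **not** emulate: recruitment channels and non-response;
demographic confounding of health risks; within-worker consistency
between, say, BMI and physical-activity responses beyond the copula
correlation; or the published per-week loss *means* (see the presenteeism
scale note above — only the zero fractions and the loss ordering are
calibration targets). Passing tests on this cohort therefore demonstrate
that the arithmetic, classification logic and estimators are correct and
well-calibrated under the assumed data-generating process — not that the
package will reproduce any particular survey's point estimates.

## Numerical choices

- Currency arithmetic is double precision throughout, rounded only for
  display; published-table verification tolerances are ±0.5 AUD for
  per-worker cells recomputed from inputs printed at 2 dp, 0.01% relative
  for per-1000 cells, and exact-to-the-cent for column totals.
- Ranks use the average-rank method with tie-corrected variances
  everywhere; a zero rank-test variance (all values identical) returns
  z = 0, p = 1.
- The hurdle-intercept calibration integrates on a 121-point grid over
  [−6, 6] on the latent factor and enumerates flag combinations with
  non-zero effects; root-finding tolerance 1e−10.
- Degenerate inputs are first-class: prevalence 0 or 1 produce constant
  flags; zero PSA SEs produce point-mass draws; all-zero or all-positive
  outcomes make the two-part model abort with an informative error.

## Verification against published results

`golden_tables_check()` re-derives every cost figure of a published FIFO
mining workforce costing study from that study's own printed inputs
(bundled as plain-text fixtures): 55 of 56 figures reproduce within
tolerance. The one exception is a per-worker absenteeism cost cell for
psychological distress whose printed value (2789.49) disagrees with its
own printed excess × salary (2780.49) by exactly AUD 9 — a digit
transposition in print, which the check reports as a failure rather than
special-casing. The published column mean built from that cell is
nevertheless reproduced, since averaging the printed cells includes the
transposed digit.

## Problem sizes used by the test suite

The suite verifies calibration at n = 50,000 (prevalences within 1
percentage point), survey-scale margins at n = 216 across seeds
(binomial bands around 20.4%/53.7%), two-part parameter recovery at
n = 50,000 (within 2 SE of the generator's hurdle log-odds and
positive-part increment), Wald CI coverage over 500 null-generator seeds
at n = 800 (95% ± 2 pp pooled over the eight condition coefficients),
WPAI formulas against a rational-arithmetic oracle on 10⁴ random integer
inputs, rank statistics against exhaustive-permutation oracles for all
n ≤ 8, and PSA mean recovery within 0.5% at 1000 draws. These sizes were
chosen so each property is tested at a scale where its asymptotic claim
should hold to the stated tolerance.

## Known limitations

- The human-capital approach values time at the average wage; wage
  heterogeneity across roles and part-time work are not modelled.
- The adjusted excess comes from OLS on a zero-inflated percentage
  outcome; the two-part model is provided precisely because OLS on such
  outcomes is a linear approximation, but the costing pathway follows the
  applied convention of using the OLS coefficients.
- Wald intervals for the logistic part can undercover in very small or
  sparse samples; the coverage simulation runs at n = 800, not n = 216.
- The PSA propagates only coefficient and prevalence uncertainty; salary
  is treated as fixed.
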