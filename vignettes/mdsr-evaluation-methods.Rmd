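---
title: "Methods: scoring, indexing and testing MDSR system performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, indexing and testing MDSR system performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdsrpi)
```

## The evaluation model

Maternal Death Surveillance and Response (MDSR) is a notification–review–
response cycle: facilities notify maternal deaths weekly through the
public-health emergency reporting channel, committees investigate them
(verbal autopsy for community deaths, facility abstraction forms for
facility deaths) and the reviews flow to a national hub. This package
evaluates such a system on two complementary axes.

**Readiness** asks whether a facility has the machinery to run the cycle.
Each facility answers a yes/no checklist with four dimensions: structure
(7 items), core function (11), supportive function (10) and system
attributes (26 items in five subcategories — simplicity 7, flexibility 2,
acceptability 5, usefulness 8, stability 4). A dimension score is the
pooled percentage of "yes" answers; the overall score is the weighted sum
of the four dimension percentages with equal default weights, so it equals
their mean. Scores map onto the Ethiopian Public Health Institute (EPHI)
mid-term evaluation bands, from "not functioning" (at most 20%) to "very
effectively functioning" (above 90%).

The attributes dimension pools all 26 items rather than averaging the five
subcategory means; the subcategory percentages are computed and reported
alongside, because the subcategories have very different sizes (2 to 8
items) and a mean-of-means would implicitly reweight them.

**Performance** asks what the system actually did, from the count cascade
per region: expected deaths $E(d)$ (an input, estimated externally from
population projections and mortality models — never estimated here),
identified deaths $d_i$ (from parallel data sources such as routine health
information systems), notified $d_n$, reviewed $d_r$, and the community/
facility split of the reviewed deaths. Five indicator rates are formed
(notification rate $R_n = d_n/d_i$, notification coverage $CR_n =
d_n/E(d)$, review coverage $CR_r = d_r/E(d)$, review rate $R_r = d_r/d_n$,
community share $CRD_p = d_{rc}/d_r$, all on the percent scale) and
combined into the MDSR Performance Index with weights 0.1, 0.3, 0.3, 0.2,
0.1: the coverage rates carry the most weight because they measure
representativeness, the system's ability to see the true death burden.
The index classifies as low below 0.4 (fraction scale), moderate between
0.4 and 0.6, and good above 0.6.

Two modelling facts about the indicators deserve emphasis:

* $R_r$ can exceed 100% and is deliberately never capped, not even inside
  the composite. Review committees review deaths that were never notified
  through the weekly channel, so $d_r > d_n$ is a real, informative state
  (Tigray's 213.6% is the extreme in the packaged panel), and capping it
  would change the published index values.
* National indicators are computed from nationally summed numerators and
  denominators, not by averaging regional rates — the indicators are
  ratio statistics and regions differ enormously in size.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| dimension weights | 0.25 each | fraction | equal weighting of the four readiness dimensions |
| MDSRPI weights | 0.1/0.3/0.3/0.2/0.1 | fraction | representativeness-first weighting fixed by the national technical working group |
| EPHI bands | 20/50/75/90 | % | institutional rating scale |
| index class cuts | 0.4, 0.6 | fraction | low/moderate/good convention |
| `alpha` | 0.05 | — | two-sided significance level |
| `rounding_decimals` | 1 | digits | display rounding of published-style tables |
| implementing rule | notified ≥ 1 and reviewed ≥ 1 | deaths/year | defines an MDSR-implementing facility |

All composite arithmetic runs unrounded; rounding (half away from zero,
because base R's half-to-even would not reproduce table values such as
44.925 → 44.9) is applied only at display and report time.

## Numerical and design choices

Several places in the published procedure are ambiguous; the package fixes
each one deterministically.

* **EPHI band endpoints.** The stated integer bands ("21 to 50%", "51 to
  75%") leave fractional scores such as 50.4 unassigned. The bands are
  implemented as half-open intervals with closed upper bounds
  ((20, 50], (50, 75], …), which covers all of [0, 100] and agrees with a
  national core-function score of exactly 20.0 rating "not functioning".
* **Index class endpoints.** "Between 0.4 and 0.6" is read as the closed
  interval [0.4, 0.6]; no region in the packaged panel sits on either
  endpoint, so the choice is about totality, not about reproducing a
  value.
* **Expected-deaths total.** The published regional expected-deaths
  values sum to 60,639 while the published national total is 60,686. The
  packaged panel stores the regional values as printed and carries the
  printed national total as an attribute, which national aggregation uses
  by default; recomputing from the regional sum is available via the
  `expected_total` argument. The discrepancy moves the national coverage
  rates by less than 0.01 percentage points.
* **Group comparisons.** The pooled-variance (Student) t-test is the
  default, matching the classical ANOVA identity $F = t^2$ used in the
  test-suite; Welch is a switch. Confidence intervals on group means use
  the normal ±1.96·SE form, which reproduces the published intervals
  exactly; no t-quantile. The Bonferroni family is all pairwise contrasts
  within one characteristic, and the family size is recorded on the
  result. The Shapiro–Wilk gate is advisory (a warning), since parametric
  tests are reported throughout the published workflow.
* **Trend testing.** Mann–Kendall uses the tie-corrected variance and the
  ±1 continuity correction (switchable). Sen's slope confidence bounds use
  the rank method tied to the Mann–Kendall variance, with linear
  interpolation between adjacent order statistics and clamping to the
  observed slope range — deterministic where the textbook procedure leaves
  interpolation unstated. The module is unit-agnostic: slopes are in units
  of the supplied series per year.
* **Survey-design arithmetic.** Stratum sizes round up (conservative
  coverage) and are capped at the stratum population; the design effect
  multiplies the finite-population-corrected size by default, with a
  switch to inflate the initial size instead, since the displayed formula
  is ambiguous about ordering. PPS allocation integerises by largest
  remainder with deterministic tie-breaking by region order, so the
  allocation sums to the total exactly. The variance, margin of error and
  critical value behind any particular published sample size are required
  inputs with no defaults: they are not recoverable from the printed
  record, so totals like 552 health centres + 77 hospitals are accepted
  as configuration rather than reproduced.
* **Zero denominators** leave an indicator `NA` ("undefined"), never 0 or
  infinity, and the composite refuses to form until every indicator is
  defined, naming the offending ones.
* **Missing or malformed items** are hard errors naming the row and
  column; no imputation, since the source workflow reports none.

## What the synthetic generator emulates — and what it does not

`synth_config()` defaults to an "ethiopia2020" profile fixed once from the
published record: 400 facilities distributed over 11 regions with the
published categorical mixes; item responses drawn i.i.d. Bernoulli within
each dimension at the published national dimension means (0.517, 0.200,
0.384, 0.696); an implementing probability of 0.77; a per-region binomial
cascade (identify → notify/review → community split) at the national
cascade ratios; and a community-review share falling linearly from 100%
at 8.33 points per year over 2013–2020 with Gaussian noise (SD 5,
a realistic year-to-year wobble for a proportion series of this kind).

Reviewed deaths are drawn from *identified* deaths, not from notified
ones, so that review rates above 100% — a structural feature of the real
system — are reachable in simulation. This is a modelling device, not a
claim about the real review process.

The generator deliberately omits features of real survey data: items
within a dimension are exchangeable (no item-level difficulty profile,
though a per-dimension probability override exists), responses are
independent across items and facilities (no intra-region correlation of
item responses), and the cascade draws are independent across regions and
years. Passing parameter-recovery tests therefore demonstrates that the
pipeline arithmetic is faithful — configured means and probabilities come
back within Monte-Carlo error — not that the pipeline is robust to
clustered, heterogeneous real-world data.

## Problem sizes used by the test-suite

The suite exercises the full published 11-region panel exactly; one
400-facility synthetic survey for dimension-mean recovery; 200 replicate
count panels for cascade-probability recovery; 500 replicate 8-year series
for slope recovery; 10,000 null replicates (n = 30 + 30) for the type-I
calibration of the pooled t-test; and 200 seeded series of length 3–8 for
brute-force equivalence of the Mann–Kendall score and Sen's slope. These
sizes keep every Monte-Carlo standard error small relative to the
tolerances being asserted.

## Known limitations

* The 54 checklist items are positional: the published instrument's item
  wording lives in unpublished appendices, so item semantics are abstract
  and item-level analyses are out of reach.
* Published per-stratum standard errors and p-values cannot be recomputed
  exactly without the facility microdata; the summary-statistic normal
  approximation (`compare_from_summaries()`) checks order-of-magnitude
  agreement only.
* The exact yearly values behind the published review-source trend are
  not printed; the trend module is validated against brute-force
  enumeration and by qualitative agreement (a significant decline) on a
  series matching the printed endpoints.
* Analyses are unweighted: survey weights from the multi-stage design are
  out of scope, matching the published analysis.
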