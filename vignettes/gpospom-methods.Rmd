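---
title: "Scoring and validating POSPOM on coded hospital case data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating POSPOM on coded hospital case data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpospom)
```

## The model

The Preoperative Score to Predict Postoperative Mortality (POSPOM) is an
additive integer point score for the risk of in-hospital death after surgery.
For a hospital case with age $a$, coded diagnoses $D$ (ICD-10) and coded
procedures $P$ (OPS, the German procedure classification), the score is

$$ S \;=\; \underbrace{\mathrm{pts}_{\mathrm{age}}(a)}_{\text{one age band}}
   \;+\; \underbrace{\sum_{g=1}^{15} \mathrm{pts}_g \,
   \mathbf{1}\{D \cap \mathrm{prefixes}_g \neq \emptyset\}}_{\text{comorbidity groups, each at most once}}
   \;+\; \underbrace{\mathrm{pts}_{\mathrm{surg}}(P)}_{\text{one index surgery}} $$

Three things make this a *table-driven* computation rather than a formula:
the age bands, the 15 comorbidity groups (sets of ICD-10 code prefixes with a
point value each), and the index-surgery categories (sets of OPS code
prefixes with a point value each) are configuration. The package deliberately
does **not** hard-code the published point values: they live in a
supplementary table of the original publication and in institution-specific
adaptations, and transcribing them silently would present a possible
transcription error as ground truth. Instead the package ships a JSON-Schema
for the table format, a filled-in toy table for tests and examples, a
template with 15 empty comorbidity slots (`inst/extdata/pospom_template.yaml`)
for users to fill, and a clearly labelled *synthetic* default table
(`default_point_table()`) whose structure — six age bands, 15 comorbidity
groups, eight surgery groups, every integer score attainable from 0 to 65 —
lets the whole pipeline run and be tested end to end.

A code matches a prefix iff the normalized code (uppercase, dots and
whitespace stripped; hyphens are structural in OPS and kept) starts with the
normalized prefix. This mirrors how ICD/OPS hierarchies and grouper tables
are written, and makes matching independent of the punctuation dialect of a
particular billing export. Each comorbidity group can fire at most once per
case, so duplicated or multiply-specific coding never inflates the score; all
15 groups may co-occur.

## Eligibility cascade

Cases flow through three sequential exclusions, in the order a registry flow
chart presents them:

1. **No index procedure** — no OPS code matches any surgery group.
2. **Under 18** — the score is defined for adults only.
3. **Incomplete** — age or discharge disposition missing. An *empty* ICD
   list is not missing: absence of coded comorbidity is informative.

Sequential means each case is counted in exactly one bucket, the earliest one
it fails; only then do the four bucket counts partition the input, which is
what makes flow-chart arithmetic reconcile. Two corner cases are fixed by
design: a case that is both a minor and incomplete lands in the minor bucket
(the earlier step), and a case with *missing* age cannot be asserted to be a
minor and falls through to the incomplete bucket.

## Index-surgery assignment

Multiply-operated cases are assigned their *first* index surgery: among
procedures matching any surgery group, the earliest procedure date wins.
Procedures tied on that earliest date — and the situation where no dates are
recorded at all, which is treated as everything being simultaneous — are
resolved toward the group scoring the **most** points. Two further rules are
this package's own determinism choices where the convention is silent: a
procedure with a missing date in a case that also has dated procedures is
treated as tied with the earliest dated one (the simultaneity reading
extended to partial information), and a residual tie on date *and* points is
broken by lexicographic group name. The table validator rejects surgery
groups whose prefix sets could both match one identical full code, so the
code-to-group assignment itself is always unambiguous.

## Outcome and validation battery

The endpoint is in-hospital death, derived from the discharge disposition:
`died` iff the discharge-reason code is in the configured death-code set
(default `"07"`, the German paragraph-21 billing convention; overridable).

* **Discrimination** — the c-statistic, i.e. the probability that a random
  death outscores a random survivor with ties counted half. It is computed
  by the midrank (Mann–Whitney) formula, which is algebraically identical to
  the pairwise definition; the test suite verifies exact equality against a
  brute-force pairwise oracle and against `pROC`. The ROC curve thresholds at
  every distinct score, and its trapezoidal area equals the same statistic.
* **Accuracy** — the Brier score, the mean squared difference between
  predicted probability and outcome.
* **Calibration** — one point per score value, predicted mortality (from the
  risk map) against observed mortality, with an ordinary least-squares line;
  slope 1 and intercept 0 is perfect calibration.
* **Descriptives** — mortality with a Wald normal-approximation confidence
  interval, mean/SD/median of score and age overall and per sex, the point
  decomposition (share of all points contributed by age, comorbidity and
  surgery), and per-score mortality. Sex strata that do not sum to the cohort
  total (unknown sex) are *reported* as a shortfall, never silently repaired.

The score-to-probability **risk map** is configuration with two modes: a
per-score lookup table (validated to cover every attainable score) or a
logistic equation $p = \operatorname{logit}^{-1}(\alpha + \beta S)$. The
package default, `default_risk_map()`, fits $\alpha$ and $\beta$ by least
squares on the logit scale through four published observed-mortality anchors
(0.31% at 10 points, 1.39% at 20, 6.35% at 30, 18.37% at 40), giving
$\alpha \approx -7.158$, $\beta \approx 0.144$ per point.

### Numerical conventions

* Percentages round half away from zero to 2 decimals (`round_half_up()`),
  matching how clinical reports print them; JSON reports additionally carry
  the exact counts so everything can be recomputed at full precision.
* SDs use the sample ($n-1$) denominator, the epidemiology convention.
* The CI method is Wald: at registry scale ($n \approx 2\times10^5$,
  $p \approx 2\%$) it is indistinguishable from exact methods and reproduces
  the conventional printed intervals.
* Degenerate inputs fail loudly with typed conditions: single-class outcomes
  (undefined c-statistic), empty cohorts, scores missing from a table-mode
  risk map, unattainable generator targets.

### Which calibration estimator for what

`calibration_fit()` defaults to the **unweighted** fit — one dot per score
value, exactly the line a calibration plot draws — and offers a
**case-weighted** variant (`weighted = TRUE`). These answer different
questions. The unweighted line describes the plotted dots, but in a
simulated cohort its extreme score bins hold a handful of cases whose
observed rates are nearly pure noise at maximal leverage; at $n = 50{,}000$
under the default generator its Monte-Carlo spread is roughly $\pm 0.3$
around 1. The weighted fit down-weights those bins by their information
content and concentrates near slope 1 within a few hundredths at the same
$n$. The package therefore uses the unweighted line for plots (and reports
it in the JSON), and the weighted line wherever the question is *parameter
recovery* — "does the pipeline recover the generating link?" — as in the
acceptance checks.

## The synthetic registry generator

No patient-level data of this kind are publicly deposited, so the package
generates registries with the statistical structure the analysis assumes.

**Scores first, codes second.** `generate_statistical()` draws each case's
integer score from a discretized truncated normal (defaults mean 18.18, SD
8.11 — the score distribution reported for a large German single-centre
cohort), then *constructs* an age, diagnosis list and procedure list that
score exactly that value (`codes_for_score()`, backed by a subset-sum
dynamic program over the table's point values). This inverse construction
gives exact control of the score distribution the validation consumes; the
test suite verifies the round trip — pipeline score equals intended score —
case by case. In-hospital death is then drawn as Bernoulli of the outcome
link (a risk map, default `default_risk_map()`), so discrimination and
calibration have a known truth to be checked against.

**Truncation is not free.** Truncating a normal with mean 18.18 and SD 8.11
at score 0 removes about 1% of its lower tail and raises the distribution's
exact mean by about +0.23. The generator keeps the conventional parameters
and exposes `score_distribution_pmf()`, the exact probability mass function
of the discretized truncated distribution, so tests compare empirical
moments against the distribution actually being sampled rather than against
the raw location parameter.

**The attrition fixture.** `generate_fixture()` builds a registry with exact
stratum counts — defaults are the flow-chart counts of the German validation
study: 357,861 cases, 115,281 without an index procedure, 41,836 minors, 964
incomplete, 4,053 deaths among the 199,780 included — so the cascade's
accounting can be exercised at full scale (a few seconds). Ages are uniform
within bands (open-ended bands use a 14-year span), sex is Bernoulli with
the reported female share 49.24%, independent of score by default.

**What the generator does not emulate**, and hence what passing tests do
*not* show about real data: the real score distribution is right-skewed, not
normal; real ICD/OPS code frequencies, coding depth and data-quality
artefacts (under-coded diabetes and hypertension, ward-to-ward variability)
are absent; cases are independent, with no patient linkage across stays, no
temporal drift over the study years, and no sex–score dependence unless
configured. The generator validates that the *pipeline* is correct, not that
the score transports to any particular population.

## Problem sizes and determinism

The test suite runs the attrition fixture at its full 357,861-case size, the
link-recovery simulation at 50,000 cases, the code/score round trip on
10,000 draws, and the pairwise c-statistic oracle on 200 random cohorts of
up to 200 cases; the whole suite completes in well under a minute on one
core. Every stochastic step sits behind an explicit integer seed
(`fixture_spec(seed=)`, `cohort_spec(seed=)`), and identical spec + seed
yields byte-identical registries and reports.

## Known limitations

* The published point values must be supplied by the user; results with the
  synthetic default table are structurally, not clinically, meaningful.
* Only the in-hospital endpoint is supported (no 30/90-day mortality), and
  no recalibration or refitting of the score is attempted.
* The mapping from procedure categories of the original French definition to
  OPS codes is institution work product; the package models only its schema.
* Transfers and readmissions are treated as independent cases, the natural
  reading of case-level billing extracts.
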