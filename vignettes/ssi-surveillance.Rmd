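---
title: "Semi-automated surveillance of deep SSI after colorectal surgery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated surveillance of deep SSI after colorectal surgery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssisentinel)
```

## The surveillance problem

Deep and organ/space surgical site infections (SSI) after colorectal surgery
are common, serious, and expensive to count: conventional surveillance means
an infection-control practitioner reads every chart. Semi-automated
surveillance replaces most of that reading with a deterministic rule over
routinely collected electronic health record (EHR) signals. Every surgery is
classified as *low* or *high* probability of deep SSI; low-probability
records are accepted as non-cases without review, and only high-probability
records go to manual chart review. The rule therefore has to be tuned for
sensitivity — a missed case is never recovered — while the fraction of
records it sends to review determines the residual workload.

`ssisentinel` implements this design end to end: a typed tabular data model
for the EHR extracts, extraction of the five binary surveillance components,
declarative high/low classification rules (with the two published rule sets
as built-ins), diagnostic-performance evaluation against a chart-review
reference standard, and a calibrated synthetic cohort generator so the whole
pipeline can be developed and tested with no access to patient data.

## Day-index convention and the follow-up window

All temporal logic runs on a day-index scale anchored at the surgery:
`day_index = (event date − surgery date) + 1`, so the surgery day is day 1,
the day before is day 0, and the follow-up (FU) window is day 1 through 45
inclusive. A single anchor keeps the two exclusion clauses in the component
definitions coherent: "starting after day 1" means first day ≥ 2, and
"prior to day 1" means day index ≤ 0. Within-day ordering is not modelled;
dates are calendar dates. An alternative half-open window was rejected to
keep the edge cases (day 1 and day 45 both count) simple and documented.

## The five components

For each index surgery, with events linked by patient identifier:

* **Admissions** — true if (a) the *index admission* (the earliest episode
  whose interval contains the surgery date) keeps the patient in hospital at
  least 14 days past the surgery, has no discharge date, or discharges after
  the FU window; or (b) a later episode readmits the patient to the original
  department within day 1–45; or (c) an in-hospital death, dated by its
  episode's discharge date, falls within day 1–45. Length of stay is counted
  from the surgery, not from admission, because surveillance is anchored at
  the surgery; `surveillance_config(los_from = "admission")` switches the
  anchor for settings that counted from admission. When no episode contains
  the surgery date, arms (b) and (c) are still evaluated and a warning of
  class `ssi_no_index_admission` is recorded.
* **Reoperation** — any procedure by the original surgery specialty on day
  2–45. Day 1 is excluded so the index procedure itself never counts; a true
  same-day reoperation is not representable at day resolution (a documented
  limitation).
* **Radiology** — at least one CT order on day 1–45. The modality set is
  configurable (`radiology_modalities`); whether the source algorithms
  restricted to abdominal/pelvic CT is not published, so modality-only
  filtering is the default.
* **Antibiotics** — at least 3 *consecutive* calendar days of systemic
  antibacterials (ATC prefix `J01`) lying entirely within day 2–45.
  Administrations are reduced to distinct day indices; doses and routes are
  ignored. Days ≤ 1 contribute nothing (perioperative prophylaxis), and days
  beyond 45 are truncated before the length test. The "any qualifying
  window" reading was chosen over "the whole course must start after day 1"
  because it is monotone — adding an administration can never switch the
  component off — and because a course running continuously from the surgery
  day for four or more days plainly contains three treatment days after the
  surgery day. A 3-day course starting on the surgery day still does not
  qualify.
* **Microbiology** — at least one culture from a relevant body site on day
  1–45 (the surgery day counts; earlier days never do). The source
  algorithms do not enumerate "relevant" sites, so the package ships an
  editable default (`default_relevant_sites()`: abdominal, pelvic, wound,
  drain, blood) used only when the input carries no explicit
  `relevant_site` flag.

## Classification rules

The published flow diagrams are not available as formulas, so rules are
modelled declaratively as a triple *(required set, optional set, minimum
optional count)*: a surgery is high probability iff every required component
is present and at least `min_optional` optional components are present. The
built-ins are

* `original` — required {microbiology}, at least 1 of the other four:
  a relevant-site culture is necessary but never sufficient;
* `adapted` — no required set, at least 2 of {admissions, reoperation,
  radiology, antibiotics}: the rule set for settings where culturing
  practice is not standard in suspected deep SSI.

These threshold forms reproduce the classifications the external validation
reports — SSI cases with 2–3 components but no culture are low under
`original` and high under `adapted`, and a zero-component case is low under
both — but the `adapted` threshold of 2 is an inference, not a published
constant; users reconstructing the exact source diagrams should encode them
with `ssi_rule()` or a YAML rule file. Classification is purely Boolean:
there is no score and hence no tie-breaking. Both built-ins, and any rule
expressible in this form, are monotone: turning a component on can never
demote a high classification.

## Performance evaluation

Against the reference standard (deep SSI within 30 days, chart review), with
high probability as the positive class:

* sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
  NPV `tn/(tn+fn)`, each with a **Wilson score interval** on its own
  denominator. With `p̂ = k/n` and `z` the standard-normal quantile at
  `(1+level)/2` (full double precision, not 1.96), the interval is
  `(p̂ + z²/2n)/(1 + z²/n) ± z·sqrt(p̂(1−p̂)/n + z²/4n²)/(1 + z²/n)`.
  The bounds are closed at the boundaries (`k = 0` → lower bound exactly 0,
  `k = n` → upper bound exactly 1); floating-point evaluation can otherwise
  land an ulp inside.
* **workload reduction** `(tn+fn)/n`: the fraction of records exempt from
  manual review. Note one printed-rounding quirk: counts (34, 25, 7, 159)
  give 166/225 = 73.78%, which this package reports as 73.8 (round half up,
  one decimal); the corresponding published table prints 73.7.
* **Cohen's kappa** and percent agreement for the double-annotated overlap,
  two raters and two categories only, `κ = (p_o − p_e)/(1 − p_e)` with
  `p_e` from the marginal label frequencies. When both raters are constant
  and identical, κ is reported as undefined rather than 1 or 0.
* A metric with a zero denominator (e.g. PPV when nothing is classified
  high) is reported as missing with an `undefined` flag, never silently as
  0 or 1.

All stored values are full precision; rounding (half up, one decimal on
percentages) happens only in `render_report()`'s text table. `report.json`
carries full precision and is byte-stable across reruns.

## The synthetic cohort generator

The generator emulates the *statistical* structure of the validation cohort,
not any real patient trajectory. Per surgery it draws deep-SSI status as
Bernoulli(0.182), then the five component indicators conditionally
independent given SSI status, then realizes each true indicator as events
satisfying the component predicate with dates uniform in their legal
windows, and each false indicator as non-qualifying distractors only
(prophylactic antibiotic courses ending by day 3, isolated antibiotic days
at least three days apart, non-J01 courses, pre-operative or
non-relevant-site cultures, non-CT imaging, other-department readmissions,
wrong-specialty or post-window reoperations). An index admission is always
emitted. This makes the extraction layer testable by construction:
`extract_components()` must reproduce the planted indicator matrix exactly,
for every seed.

Conditional independence given SSI status is a modelling simplification —
only the marginal component prevalences are published, and this is the
minimal structure that lets both rules be exercised. The conditional table
is fully overridable. `P(component | SSI)` defaults to
`(0.833, 0.415, 0.936, 0.863, 0.831)` for (admissions, reoperation,
radiology, antibiotics, microbiology); these were fixed once by a
least-squares calibration (Nelder–Mead over logits) under the exact-marginal
constraint, targeting the published sensitivities and specificities of the
two rules, and give expected operating characteristics of 83.0/85.7
(sensitivity/specificity, original) and 97.6/69.7 (adapted).
`P(component | no SSI)` is derived at run time from
`m = p·q₁ + (1−p)·q₀`, so the marginals are exact by construction;
incompatible combinations are rejected at configuration time. Because every
`P(component | SSI) < 1`, the generator reproduces the "SSI with zero
components" phenomenon that defeats both rules, without special-casing.

Other generator choices: one patient per surgery (the cohort is indexed by
surgery, and planted-truth round trips need unambiguous event attribution);
a true admissions indicator is realized as prolonged stay, readmission or
death with probabilities 0.60/0.35/0.05, the death share chosen so
cohort-level in-hospital mortality is about 2%; covariates (age, sex, BMI,
ASA class, wound class, duration, stoma/primary/open/malignancy flags) are
drawn from simple parametric families matched to the published medians and
proportions and are pure passthrough — no algorithm reads them; event dates
have no seasonality; randomness uses a master seed with fixed per-stream
substreams, so adding an event type does not perturb existing draws.

What passing tests on synthetic data do **not** show: robustness to real
EHR messiness (transfers between departments mid-episode, correlated
components such as reoperation-with-culture, antibiotic switches across
ATC classes, coding errors), to patients with multiple index surgeries, or
to the free-text-only presentations that structured components cannot see:
a deep SSI documented solely in a clinical note is a recognized failure
mode of any structured-data rule and is out of scope here by design.

## Problem sizes and numerical checks

The test suite runs entirely on generated data: exhaustive 32-profile truth
tables for the classifier; 1,000 random day sets against a naive day-by-day
scan for the antibiotic-run logic; a 10⁴-point grid against an independent
quadratic-root formulation for the Wilson interval (agreement within 1e-9);
planted-indicator round trips over 10 seeds of the default 225-surgery
cohort; and calibration summaries over 500 sampled cohorts of 225 (SSI
prevalence within 1 percentage point of 18.2%, component marginals within 3
standard errors, adapted sensitivity above original, original workload
reduction above adapted). `scripts/acceptance.R` repeats the headline
computations from scratch — the performance table from its confusion
counts, event-level pipeline calibration over 60 simulated cohorts, and a
500-replicate double-annotation simulation — and writes them as JSON.

## Known limitations

* The rule model covers threshold-style combination rules; an arbitrary
  decision tree over components would need a custom predicate.
* Day resolution cannot represent same-day reoperations or within-day
  ordering.
* Kappa is two-rater/two-category; no weighting, no multi-rater designs.
* The generator's conditional-independence assumption understates the
  clinical correlation between, e.g., reoperation and culturing; joint
  dependence is left to user-supplied conditional tables.
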