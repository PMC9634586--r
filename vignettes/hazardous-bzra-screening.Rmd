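---
title: "Screening prescription records for hazardous hypnotic use: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening prescription records for hazardous hypnotic use: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzrascreen)
```

## The problem

Benzodiazepine receptor agonists (benzodiazepines and Z-drugs) are
recommended for short courses — typically 2 to 4 weeks — yet tolerance and
dependence develop within weeks to months of continuous use. Where
hypnotics are tightly controlled, patients refill prescriptions at
hospital out-patient clinics, so a year of dispensing records is a
faithful record of supplied drug. `bzrascreen` reconstructs individual
exposure from such records and applies transparent rules to flag
prescribing patterns inconsistent with recommendations: sustained high
dose, long uninterrupted use, their conjunction ("hazardous use"), and
dispensing unsupported by any recorded diagnosis ("over-indication use").

## Exposure model

All doses are expressed in diazepam milligram equivalents (DME) so that
drugs of very different potency are comparable; conversion is linear,
`dme = dose_mg × dme_per_mg(drug)`. The default registry fixes the three
anchored conversions (clonazepam 20 DME/mg, zolpidem 0.5 DME/mg,
lorazepam 10 DME/mg, diazepam 1 by definition); the remaining factors
follow a published 10-mg-diazepam-reference equivalence table and the
DDDs the WHO ATC/DDD index. These non-anchored values are data, not
logic: they live in the registry with a provenance string and are
overridable by a YAML config, and correctness claims bind only to the
anchors.

A patient's **daily dose array** assigns to each calendar day the sum of
daily DME of every prescription covering that day, over the closed
interval `[visit_date, visit_date + days_supplied − 1]`, truncated at
Dec 31. Two design choices deserve comment:

- **Overlaps stack.** When refills overlap, daily doses add. The
  alternative — carrying unused supply forward — would model adherence we
  cannot observe. Batching of refills is instead neutralised by the
  windowed maximum below, which is why that statistic exists: patients
  who collect several months of supply at once would otherwise appear to
  take extreme daily doses.
- **Day-level resolution.** Multiple same-day dispensings sum; time of
  day is ignored.

Per-patient statistics derived from the array:

| statistic | definition | default |
|---|---|---|
| `max_window_avg_dme` | max over all 90-day windows of the window mean (calendar-day denominator; non-use days count as zero) | window = 90 d |
| `max_continuous_days` | calendar span of the longest episode after merging use-runs separated by ≤ `max_gap` non-use days | gap = 3 d |
| `total_dme`, `total_days_of_use` | array sum; count of positive days | — |
| `n_visits`, `n_distinct_doctors` | distinct (date, doctor) dispensing events; distinct prescribers | — |
| `average_daily_dme` | `total_dme / total_days_of_use` | — |

The "3-month" averaging period is operationalised as a sliding 90-day
window with denominator 90. A use-day denominator variant would conflate
dose with duration; with typical daily doses near 10 DME and episodes of
a month, only the calendar-day denominator yields the low cohort medians
(≈ 4 DME/day) characteristic of short-term users. The episode length
counts bridged gap days (calendar span), reading the statistic as the
duration of an episode of use; the 3-day tolerance reflects the 72-hour
window in which withdrawal symptoms peak, so a patient pausing two days
between refills is still one episode.

## Classification rules

- **Overdose use**: `max_window_avg_dme > 40` (strict — "more than 40").
- **Long-term use**: `max_continuous_days ≥ 90` (inclusive). With 30-day
  prescription limits, three back-to-back maximal prescriptions reach
  exactly 90 days; the inclusive reading makes precisely that minimal
  refill pattern qualify. Both thresholds are arguments, not constants.
- **Hazardous use** is their conjunction, by definition, and partitions
  the cohort.
- **Over-indication use** is patient-level: diagnoses are pooled over the
  year and a patient is flagged only if *no* pooled diagnosis
  prefix-matches *any* approved indication of *any* dispensed drug.
  Pooling is deliberate: indications recorded at one visit justify
  refills at another, and per-visit matching would overcount. Matching is
  by ICD-10 prefix (e.g. indication stem `G40` matches `G40.3`) because
  approved indications are published as code blocks, not full codes. A
  per-drug variant powers the "most common drugs among over-indication
  users" ranking. Patients with no usable diagnosis data return `NA` and
  are excluded from the over-indication denominator and the regression
  (soft exclusion) while remaining in the descriptive tables.

## The regression

Hazardous use is regressed on age group (reference < 18), gender
(reference female), region (a hospital attribute; reference east),
over-indication use, annual visit count and distinct-doctor count, with
a hospital random intercept because patients are nested within
hospitals. The default family is a **linear probability model** fitted
by REML (`lme4::lmer`): reported coefficients of hazardous-use
predictors in this literature are small symmetric risk differences
(0.005–0.018) with narrow CIs, the signature of an identity link. A
logistic variant (`lme4::glmer`) is provided; on weak effects the two
agree in sign (tested). Confidence intervals are Wald-type at 95%; no
multiplicity adjustment is applied. Estimation is deterministic given
the design.

Two caveats are surfaced rather than hidden. With only a handful of
hospitals, region (a hospital-level covariate) and the hospital random
intercept are weakly identified; the fitter emits a message. And with
rare outcomes the linear probability model can predict outside [0, 1];
it is used for effect estimation, not individual prediction.

## The synthetic generator

Real dispensing databases of this kind are not shareable, so validation
runs on synthetic cohorts whose ground truth is known. The generator
(`cohort_config()`, `generate_cohort()`) draws each patient from one
archetype:

- *casual* (82%): 1–3 non-overlapping courses of 7–30 days, lognormal
  daily doses capped at 35 DME — bounded by construction below both
  thresholds, so never hazardous;
- *long-term stable* (8%): contiguous 30-day refills spanning 100–260
  days at 5–30 DME/day — long-term, never overdose;
- *short overdose* (4%): one 20–60-day episode dosed so the best 90-day
  window exceeds 40 DME — overdose, never long-term;
- *hazardous* (3%): refills spanning 100–280 use days with occasional
  1–3-day gaps at 50–90 DME/day. At most nine gap days can fall in any
  90-day window of the episode, so the window average is at least
  81 × 50 / 90 = 45 > 40, and the merged episode span is ≥ 100 ≥ 90
  days: both flags hold *by construction*, which is what makes the
  recovery tests sharp (a rejection sampler would only make them likely);
- *doctor shopper* (3%): 8–20 short low-dose dispensings from distinct
  prescribers; dose and course bounds keep even fully overlapping
  windows below 26 DME/day.

Planted episodes are placed to fit inside the study year; supplies that
would cross Dec 31 (possible for casual tails) are kept and truncated
downstream, exercising the truncation rule. Default mixes, the 55.9%
over-indication probability, the 63.6%-female and 76.2%-aged-18–64
demographics, and five hospitals across east/central/west regions follow
the magnitudes reported for large psychiatric out-patient populations. A
2% missing-demographics rate exercises the soft-exclusion path. Dose and
refill-count distributions (lognormal doses, uniform spans) are
pragmatic choices — the source literature reports only medians and IQRs —
so passing tests demonstrate correct *mechanics* (conversion,
accumulation, episode logic, thresholds, model recovery), not
distributional realism of any real hospital's case mix.

For regression validation specifically, `simulate_hazard_design()` draws
covariates and outcomes directly from the linear-probability
random-intercept model with planted coefficients matching the reported
magnitudes (0.018, 0.015, 0.005, 0.013, 0.006, 0.007; hospital intercept
s.d. 0.01), bypassing the prescription layer so the estimand is exact.

## Numerical choices and degenerate inputs

- Window maxima use a cumulative-sum scan, O(n); tests compare against a
  naive all-windows scan at 1e−9 relative tolerance (float associativity
  is the only permitted difference). Ties between windows are resolved to
  the earliest, which is unobservable in the scalar statistic.
- Episode detection splits sorted use-day indices where consecutive
  differences exceed `max_gap + 1`; an explicit day-by-day state machine
  serves as the independent oracle. No use days ⇒ 0.
- Dose conservation — array sum equals Σ daily dose × covered days — is
  asserted at 1e−9 relative tolerance on every synthetic cohort.
- Quartiles use the linear-interpolation definition (R type 7), fixed
  because reported IQRs rarely state their convention.
- χ² tests apply the Yates correction only to 2×2 tables (configurable);
  calibration is checked on a 3×2 null at nominal 5%.
- Empty record sets: an empty CSV yields an empty cohort with a warning;
  a patient with zero records is a contract violation for
  `compute_metrics()`; a single-hospital design is refused with advice
  to fit a fixed-effect model.
- Validation is two-tier: records with unknown drugs, bad dates, or
  non-positive dose/duration are hard-excluded with a per-reason ledger;
  patients missing gender/age/diagnoses are soft-excluded (regression
  only). Multi-hospital patients are assigned to their first hospital
  for the multilevel model — a convention, since nested designs assume
  one hospital per patient.

## Problem sizes used in the validation suite

The suite runs the oracle comparison on 10,000 random arrays, archetype
recovery on two pure cohorts of 10,000 patients, prevalence recovery on
a mixed cohort of 10,000 (99% binomial bounds around the planted 3%),
coefficient recovery at n = 20,000 with 5 hospitals (each fitted β
within 2 fitted s.e. of its planted value), null-covariate coverage over
500 refits at n = 2,000 per refit, and test calibration over 1,000 null
simulations. The 2,000-patient refit size was chosen as the smallest
cohort at which the five-hospital mixed model is routinely stable; the
single recovery fit keeps the full n = 20,000.

## Known limitations

- Dispensing is not ingestion: arrays measure supplied drug; adherence,
  sharing, and out-of-system sources are invisible, so hazardous-use
  counts are lower bounds in real data.
- The non-anchored DME factors and the indication map defaults are
  illustrative; site-specific analyses should supply their own registry
  config (the anchored trio and the rule logic are unaffected).
- No pharmacokinetics: half-lives and accumulation are out of scope; a
  clonazepam day and a zaleplon day with equal DME are treated alike.
- The generator does not imitate real coding systems, brand names, or
  any specific hospital's archetype frequencies; end-to-end numbers on
  synthetic cohorts validate the instrument, not any population.
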