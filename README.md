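# bzrascreen

Screening out-patient prescription databases for hazardous use of
benzodiazepine receptor agonists (BZRAs) — benzodiazepines plus the
Z-drugs (zolpidem, zopiclone, eszopiclone, zaleplon).

Hypnotics are among the most dispensed psychoactive drugs, and because
they are tightly controlled, refill records in hospital prescription
databases give a reliable individual-level picture of consumption. This
package turns a year of dispensing records into per-patient exposure
reconstructions and rule-based risk labels, for pharmacoepidemiologists
and pharmacy administrators auditing prescribing practice.

## The method

For each patient, every dispensing is converted to **diazepam milligram
equivalents** (DME; e.g. 0.5 mg clonazepam = 10 DME) and accumulated into
a **daily dose array** `d(t)`, `t = 1, …, 365`: each prescription adds its
daily DME to every day of its coverage interval
`[visit_date, visit_date + days_supplied − 1]`, and overlapping
prescriptions stack. From the array:

- **Maximum windowed average**: `M = max_t mean(d(t), …, d(t+89))`, the
  densest 90-day exposure. Early refills and stockpiling inflate single
  days, not the whole window, so `M` is robust to prescription-batching.
  `M > 40` DME/day defines **overdose use**.
- **Longest continuous-use episode**: over the binary use vector
  (`d(t) > 0`), runs separated by ≤ 3 non-use days are merged (withdrawal
  peaks within 72 h of cessation); the longest merged calendar span `L`,
  with `L ≥ 90` days, defines **long-term use**.
- **Hazardous use** = overdose AND long-term.
- **Over-indication use**: none of the patient's recorded ICD-10
  diagnoses for the year prefix-matches any approved indication of any
  drug dispensed to them.

Cohort-level outputs mirror the standard reporting tables: demographics,
diagnosis-block distributions, median (IQR) exposure metrics, DDD
consumption by hospital and drug class, and classical group tests
(χ², Wilcoxon rank, Kruskal–Wallis). Association of hazardous use with
patient covariates is estimated by a multilevel linear-probability model
with a hospital random intercept,

```
hazardous_ij = β0 + β·x_ij + u_j + ε_ij,   u_j ~ N(0, σ²_hospital)
```

where `x` holds age group, gender, region, over-indication use, visit
count and distinct-doctor count; coefficients are risk differences. A
logistic variant is available.

Because real prescription databases of this kind cannot be shared, the
package ships a seeded synthetic generator with constructively planted
user archetypes (casual, long-term stable, short-term overdose,
hazardous, doctor-shopper), so every stage is testable end to end and
parameter recovery can be verified.

## Worked example

```r
library(bzrascreen)
cfg <- cohort_config(n_patients = 2000, seed = 42)
rec <- generate_cohort(cfg)
scr <- bzra_screen(rec, n_total_outpatients = 8000)
scr
```

```
BZRA prescription screening
  2000 patients, 5466 records, study year 2018
  thresholds: overdose > 40 DME/day (90-day window), long-term >= 90 days (gap <= 3)
  hazardous: 71 (3.55%); overdose: 174; long-term: 222; over-indication: 56.1%
```

3.55% of the simulated patients are hazardous users (the generator
plants 3%, plus sampling noise); 56.1% have no recorded diagnosis
matching an approved indication of any of their drugs. `summary(scr)`
prints the full report — per-hospital prevalence, median (IQR) exposure
metrics (e.g. median maximum windowed average 3.5 DME/day, median
longest episode 24 days: mostly short, low-dose use), drug-class shares
and the over-indication drug ranking. The regression then quantifies the
covariate associations:

```r
des <- build_design(scr$metrics, scr$labels, attr(rec, "hospitals"))
fit <- fit_hazard_model(des)
fit
```

```
Multilevel hazardous-use regression (linear_probability, hospital random intercept)
n = 1967 patients; 33 dropped for missing covariates

          covariate      beta                   ci
 ...
           n_visits  0.006420  [0.001286, 0.01155]
 n_distinct_doctors  0.015950   [0.01028, 0.02162]
```

Each extra visit raises the hazardous-use probability by about 0.6
percentage points in this cohort, each extra distinct prescriber by
about 1.6 — the doctor-shopping signal. `plot(scr)` draws the
days-of-use versus average-daily-dose scatter with hazardous users
highlighted.

A command-line wrapper is included at `inst/scripts/bzra`
(`bzra simulate | analyze | full`).

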