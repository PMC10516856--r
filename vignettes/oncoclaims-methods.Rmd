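---
title: "Claims-based oncology analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claims-based oncology analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoclaims)
```

## The problem

Administrative claims record what was billed, not what was diagnosed or
intended. To describe treatment patterns and the cost of managing a cancer
population from claims alone, three inferences have to be made explicit and
reproducible: who belongs in the cohort, what stage each patient was in at
diagnosis, and how individual drug claims aggregate into clinically
meaningful treatment lines. `oncoclaims` implements each inference as a
small, separately testable rule, and adds the per-patient-per-month (PPPM)
estimation layer used to summarise utilization and costs. The defaults
describe a triple-negative breast cancer (TNBC) population in a Brazilian
private-payer database: TNBC has no targetable receptor, so its systemic
therapy is cytotoxic chemotherapy, and the *absence* of hormone or
anti-HER2 claims is what identifies the subtype in billing data.

## Cohort selection

`select_cohort()` requires, per patient: age ≥ 18; at least one diagnosis
claim with ICD-10 prefix C50 inside the enrolment window (default
2012-01-01 to 2017-12-31); at least one drug claim for an inclusion
molecule (the TNBC chemotherapy list); no exclusion-molecule claim
(hormone/targeted therapy) at any time; and no C50 or treatment claim in
the 2011 washout year. The index date is the first in-window C50 claim.
Three choices deserve note:

* *"C50 claim" means the category prefix*, any fourth character, because
  subcode usage is inconsistent across payers.
* *The washout is evaluated on drugs as well as diagnoses.* The point of
  the rule is to exclude prevalent cases already under treatment; drug
  claims are the operational definition of "under treatment" here. Whether
  2011 *procedures* should also count is genuinely open; we restrict to
  molecule claims and diagnosis codes and document that scope.
* *Missing age retains the patient* (flagged `age_missing`): claims
  databases routinely lack demographics, and silently dropping those
  patients would bias the cohort toward payers with better data capture.

All failed rules are reported, not just the first, and the verdict is
invariant to claim order.

## Staging from claims

`classify_stage()` calls a patient metastatic when at least two qualifying
claims fall in the window from 30 days before to 183 days after the index
date with some pair ≥ 15 days apart. Qualifying claims are diagnosis codes
in C76–C80 — *except C77.3*, secondary involvement of axillary/upper-limb
nodes, which marks regional rather than distant spread — plus any claim
whose code is in the configurable metastatic-management set. Decisions:

* **Window bounds.** "One month before, six months after" is realised as
  30 and 183 days (6 × 30.4375, rounded), endpoints inclusive, consistent
  with the single month convention used everywhere else in the package.
* **Pooled evidence.** The two qualifying claims may mix kinds: one
  metastatic ICD code plus one metastatic-management procedure counts.
  This is the natural reading of "codes or related treatments/procedures",
  and the behaviour is pinned by a brute-force oracle test that enumerates
  all claim pairs.
* **Repetition suffices.** The same code on two dates qualifies; the rule
  demands repeated evidence over ≥ 15 days, not code diversity.

The classifier is monotone (adding evidence can only move a patient toward
metastatic), which the suite checks property-style.

## Lines of therapy

`build_lines()` replays the claim history date by date. Line 1 opens at
the first drug claim. Molecules claimed within the 28-day grouping window
of a line start form its regimen — 28 days spans one cycle of the 21-day
regimens that dominate this population, so a combination started across
two visits is still one regimen. Two rules open a new line, checked in
this order:

1. **Gap:** any drug claim ≥ 120 days after the previous drug claim
   (regardless of molecule);
2. **Switch:** a molecule outside the current regimen ≥ 60 days after the
   *current line's start*.

A new molecule appearing after the grouping window but before day 60
extends the current regimen: the 60-day threshold exists precisely so that
early additions are read as regimen modification, not switching. The
switch clock is anchored at line start rather than last claim because the
rule text gives no anchor and line-start anchoring is the common
line-of-therapy convention in claims work; the oracle tests over the
critical offsets (0, 14, 28, 45, 46, 59, 60, 61, 119, 120, 121 days) pin
the choice. Same-day claims are processed together, so a same-day
combination start never splits.

For early-stage patients with breast surgery, lines split around the first
surgery date into neoadjuvant (strictly before) and adjuvant (on/after)
blocks (`classify_setting()`), and follow-on regimens are tagged by
`tag_sequential_or_progression()`: a gap of ≤ 45 days from the previous
regimen's *end* is planned sequential chemotherapy, a longer gap marks
treatment for progressive disease. The 45-day clock runs from regimen end
because the sequential window plausibly bounds the treatment-free
interval, not the line-to-line distance. When the 120/60-day line rules
and the 45-day tag could interact, the implemented order is gap → switch →
tagging, recorded in the run manifest. Metastatic patients' lines are
labelled LOT1, LOT2, …; pre-surgery chemotherapy of surgical metastatic
patients is additionally labelled NAT for the neoadjuvant-share statistic
while keeping its LOT number.

## PPPM estimation

Exposure is restricted to treatment periods: claims inside any line's
closed `[start, end]` interval count, and exposure is the summed line
duration in months (`months = days / 30.4375`). A line whose start and end
coincide contributes a 0.25-month floor — a single-visit line is real
exposure, and a zero denominator is the alternative. Durations, time to
treatment initiation and time to next treatment (TTNT, start-to-start) use
the same convention, and `summarize_values()` reports mean, sample SD
(n − 1; 0 with a flag for a single value), median and the 25th–75th
percentile interval with linear interpolation between order statistics.

Event rates use the pooled estimator, total events over total
patient-months, with the exact (Garwood) Poisson interval on the total
count — `qchisq(0.025, 2k)/2` to `qchisq(0.975, 2k+2)/2`, divided by
exposure. Exact rather than normal intervals because subgroup tables
produce small counts. The mean ± SD of per-patient counts, the other view
a reader may want, is available directly from the per-patient table
(`patient_period_metrics()`); we do not additionally report a "mean of
per-patient rates" PPPM because no matching Poisson interval exists for
it, and the pooled rate is the quantity the interval describes.

Costs use the mean of per-patient PPPM costs with a moment-matched gamma
interval: shape `k = m²/v`, scale `θ = v/m` from the patient values, and
the mean of `n` such gammas is Gamma(`nk`, `θ/n`), whose 2.5% and 97.5%
quantiles bound the mean. The exact construction behind reported gamma
CIs is rarely stated; this one is simulation-tested (coverage ≈ 95% over
200 replicates of 500 gamma-distributed patients) rather than asserted.
Degenerate inputs (all-zero, zero-variance) collapse the interval to the
point. Inpatient costs sum admission and surgery claims (surgery bills to
the inpatient setting by definition); outpatient costs sum visits,
procedures and ER visits; medication costs are excluded throughout because
claim-level drug costs cannot be attributed reliably in this kind of
source; total = inpatient + outpatient is enforced as an invariant.
Nominal BRL amounts are adjusted by a single average inflation factor
(1.5769934, 2012–2017 to Mar/2023) and converted at 0.1968581 USD/BRL;
rendering rounds half-up (2 decimals for currency and rates, 1 for
percentages).

## The synthetic cohort generator

`simulate_claims()` exists so the pipeline can be validated end-to-end
with known truth. Its defaults are the study conditions the package
targets: 82.8% early/locally-advanced mix; surgery in 41.6% (early) and
37.4% (metastatic) of patients; the AT/NAT/NAT-AT split of 75.3 / 7.5 /
17.1% among early surgical patients; 21-day cycles, 4–6 per regimen;
anthracycline-dominated early menus and bevacizumab+paclitaxel-prominent
first-line metastatic menus; per-stage PPPM event rates (e.g. metastatic
ER visits 0.60, early procedures 23.15); and gamma-distributed nominal BRL
claim costs whose parameters were moment-matched once so that cohort-level
PPPM costs land at the magnitudes typical of this population (outpatient
dominating, inpatient driven by rare expensive admissions). Events are
drawn month-by-month at the configured rates *over treatment periods
only*, mirroring the exposure restriction, which makes parameter-recovery
tests exact in expectation.

Each patient draws from an independent RNG sub-stream seeded from the
global seed and the patient index, so adding patients never perturbs
existing ones. Contaminants violate exactly one selection rule each
(screening-only C50, hormone-therapy user, 2011 activity), which lets the
suite assert that each planted contaminant is rejected for precisely its
planted reason.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: coding noise and missing ICD fields;
package/bundled procedure codes that hide surgeries and radiotherapy;
censoring by death or disenrollment; regional or payer-level correlation;
dose, units and routes; metastatic-management procedure codes beyond the
synthetic placeholders (`MM001`, `MM002`). Recovery results on simulated
cohorts demonstrate the *algorithms* are implemented as specified, not
that the rules themselves are robust to real-world miscoding.

## Problem sizes and determinism

The test-suite and the acceptance script use cohorts of 40–400 patients
for behavioural tests, n = 3000 for parameter recovery (binomial
sampling puts the stage-mix share within ±2 points at that size), and 200
replicates × 500 patients for interval-coverage calibration; these sizes
were chosen as the smallest that make the statistical assertions sharp.
All randomness flows from explicit seeds; the pipeline itself is fully
deterministic, and a run manifest records every threshold
(30/183/15/28/60/120/45 days, the 0.25-month exposure floor, the month
convention and currency factors) alongside the outputs.

## Known limitations

* The inclusion/exclusion molecule lists and regimen-name map are
  editable defaults, not an authoritative formulary; real analyses must
  supply their payer's lists via `molecule_catalog()` or `read_catalog()`.
* Staging inherits the limits of claims-based inference: early patients
  treated within six months with drugs also used for metastatic disease
  can be misclassified, and nothing in the package can detect that.
* The 0.25-month exposure floor, the 28-day grouping window and the
  60-day switch anchor are conventions, all configurable; sensitivity of
  results to them is the analyst's responsibility.
* Costs are analysed at the claim level in two settings only; no
  discounting, no per-year inflation by service date (one average factor),
  no medication costs.
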