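---
title: "Inferring pregnancy episodes: model, windows and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring pregnancy episodes: model, windows and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregepi)
```

## The problem

Administrative claims and electronic health records rarely record
gestational age directly, yet pharmacoepidemiology needs to know when a
pregnancy started and how it ended to classify drug exposure by trimester.
`pregepi` infers *pregnancy episodes* — the interval from estimated last
menstrual period (LMP) to the pregnancy outcome date — from dated, coded
events in OMOP-CDM-like tables. A pregnancy episode is produced in two
sequential steps: outcome classification, then start estimation. A third
stage applies cohort inclusion rules, and a synthetic-cohort generator
provides planted ground truth so every stage is testable without access to
licensed patient data.

## Step 1: outcome classification

Outcome-bearing records are assessed per person in a fixed hierarchy —
live birth, stillbirth, ectopic pregnancy, abortion, delivery-only — and,
within a class, in date order. Diagnosis codes for births are the most
reliable signals in claims data, which is why they head the hierarchy;
bare delivery procedure codes are considered last and re-labelled live
births when accepted. A candidate record becomes an independent outcome
only if it passes three filters:

1. **Spacing.** The absolute day gap between the candidate and *every*
   already-accepted outcome must reach the configured minimum for that
   ordered pair of outcome classes (`config$spacing`, a 5×5 matrix). This
   is what collapses repeat billings of one delivery into one episode. A
   gap exactly equal to the table entry passes by default
   (`spacing_inclusive = TRUE`); a switch makes it strict.
2. **Follow-up invalidation** (all classes except live birth). An
   antenatal visit or pregnancy-confirmation record in
   `(record, record + 42]` days contradicts the putative end of pregnancy
   and discards the candidate. This window also absorbs rule-out abortion
   diagnoses billed before a preterm birth. Day 0 is excluded: same-day
   confirmation codes are part of the outcome encounter itself.
3. **Ectopic confirmation.** An ectopic record must be corroborated within
   `[record, record + 14]` days by methotrexate, ectopic-specific surgery,
   or a concept curated as ectopic-associated. Day 0 *is* included here,
   because ectopic treatment is typically administered same-day in an
   emergency fashion. The outcome date moves to the last treatment date in
   the window (an associated concept confirms without moving the date).

Abortion outcome dates are likewise reassigned to the last
abortion-category record within 14 days, so a cluster of procedure and
diagnosis billings ends the episode at its final record.

The check order is spacing → invalidation → confirmation; this order only
affects the rejection reason reported, never the accepted set.

### The spacing table is configuration

The inter-outcome minimum-day table is not printed in the source
literature's main text; the values shipped here are clinically motivated
configuration, not reproduced ground truth, and every test that depends on
them sets them explicitly (or uses these defaults knowingly). Two
principles chose them: a later live birth must be at least a minimum
gestation (~168–182 d) from any prior outcome, and short windows
(56–70 d) separate early-loss outcomes. We deliberately did **not** adopt
a short "after abortion" spacing (e.g. 14 d): that would let rule-out
abortion codes billed up to a month before a birth stand as independent
outcomes, defeating the table's stated purpose.

## Step 2: start estimation

For each accepted outcome the estimator searches back `max_term_days`
(301 for live births) and ranks the markers it finds:

| rank | marker | implied start |
|------|--------|---------------|
| 1 | last menstrual period | record date |
| 2 | gestational age record | date − (weeks × 7) |
| 3 | conception-dating fertility procedure | date − 13 |
| 4 | nuchal translucency ultrasound | date − 89 |
| 5 | alpha-fetoprotein screen | date − 123 |
| 6 | amenorrhea record | date − 55 |
| 7 | urine pregnancy test | date − 55 |
| 8 | outcome-specific average estimate | outcome − estimate |

A marker is *eligible* only if its implied term is **strictly** between the
outcome's minimum and maximum term (161 < term < 301 for live births — a
gap of exactly 301 days is ineligible), and not dated before the prior
outcome plus its "retry" period, the minimum delay before a new conception
is clinically possible. The highest-ranked category with an eligible event
wins; within a category we use the *earliest* eligible event (earliest is
closest to the true start for repeated tests; `within_category_pick`
switches this). With no eligible marker, the episode is classified preterm
if a preterm-category record lies in the search window, full-term
otherwise, and the outcome-specific average gestation is subtracted:
280 days for full-term live births, 196 for stillbirths, 70 for abortions,
56 for ectopic pregnancies. The preterm live-birth value (245) and the
retry values (28 d after births, 14 d after early losses) are not printed
in the main source text and ship as labelled configuration.

If the prior outcome date plus its retry period is later than the
estimated start, the start is clamped forward to that date.

### The adjustment rule is a reconstruction

Starts estimated by the low-confidence methods (amenorrhea, urine test,
average estimate) are adjusted against two contradicting signals, a rule
whose published specification is in an unavailable appendix; the shipped
rule is our documented reconstruction and is configurable:

* a contraceptive dispensing *after* the estimated start (but more than a
  minimum term before the outcome) moves the start to the day after the
  last such dispensing;
* a pregnancy-confirmation record *before* the estimated start moves the
  start to the confirmation date minus `confirmation_lead_days` (28 by
  default — first confirmation visits typically happen around 4 weeks of
  missed cycle).

An adjustment is suppressed rather than applied if it would push the term
outside the strict min/max bounds or before the retry clamp.

## Inclusion rules

An episode enters the final cohort when the person is female, aged 12–55
at the episode start (age anchored at start because that is the
exposure-relevant age; the source text does not pin the anchor), one
observation period covers start through outcome, and at least two
categorized pregnancy events fall inside the episode. The outcome record
itself counts toward the two by default (`count_outcome_record`): in claims
data repeat billings demonstrably reduced this exclusion, which is only
possible if outcome-category rows count.

## The disproportionality screen

The ectopic-associated concept list is curated by a prevalence-ratio
screen: a concept qualifies when its prevalence in the 60 days after an
ectopic diagnosis exceeds 5× its prevalence among reference women
(age 15–55, fully observed in a reference calendar year). Reference
prevalence is person-level (a woman counts once no matter how many
records); ectopic prevalence is window-level (each diagnosis window counts
once). Concepts never seen in the reference year but present in windows
are reported with an "infinite ratio" flag rather than silently dropped.
The reference year is a parameter, not a constant.

## What the synthetic generator does and does not emulate

`generate_cohort()` plants pregnancies with known conception-anchor
(gestational day 0) and outcome dates: outcome mix ≈ 73% live births /
25% abortions / 1.5% ectopic / 0.5% stillbirths, term lengths drawn from
truncated normals (live birth 280 ± 10 d truncated to 162–300, stillbirth
196 ± 21, abortion 70 ± 14, ectopic 56 ± 7 — the truncation keeps every
planted term strictly inside the estimator's eligibility bounds), and
markers emitted *exactly on* their guideline gestational days (nuchal 89,
AFP 123, amenorrhea/urine 55, confirmation 42) with realistic per-category
recording probabilities. Ectopic treatment is emitted same-day, matching
its emergency character. Noise switches add repeat outcome billings
(1–7 d later), rule-out abortion codes 0–30 d before preterm births,
isolated historical outcome codes, and marker dropout.

Because scheduled markers carry no jitter, a green recovery test
establishes that the *rule engine* inverts the generative schedule
exactly; it does not establish robustness to real-world marker-date error,
vocabulary mapping noise, or enrollment churn, none of which are emulated.
Recovery tests run in a "full LMP recording" variant (LMP emission
probability 1) — the noise-free stated world — so that every planted
episode passes the two-event inclusion rule without relying on billing
duplicates. The same world is used for the repeat-billing robustness
check: with default (sparser) marker recording, duplicate billings
*increase* the included-episode count by rescuing marker-poor episodes
past the two-event rule — the same interaction reported for real claims
databases — which would conflate inclusion effects with the
double-counting question that check asks.

## Numerical conventions

* All date arithmetic is whole calendar days; parsing strips any
  time-of-day component.
* "Within X days after" windows exclude day 0 and include day X —
  `(d, d+X]` — except the 14-day ectopic-confirmation/reassignment
  windows, which include day 0 (same-day treatment).
* Term eligibility is strictly exclusive at both bounds, exactly as the
  rule is stated.
* Ages are completed years; persons with only a birth year should be
  assigned July 1 before import.
* Within-category marker ties at the same date break by earliest implied
  start for determinism.
* The generator derives one sub-seed per person from the master seed, so
  person *k*'s data is invariant to `n_persons`.

## Known limitations

Source-vocabulary mapping (ICD/Read/CPT → SNOMED) is out of scope: the
package consumes an already-categorized concept table. Spontaneous vs
induced abortion is a single class, mirroring the source algorithm's
abandonment of the split. Multiple gestation is not distinguished; a
live birth plus stillbirth on one date classifies as live birth.
Mother–infant linkage is not attempted. The validation analytics
(`fertility_sensitivity()`, `marker_proximity()`, `export_profiles()`)
reproduce the *procedures* of the published validation; their published
real-data percentages derive from licensed databases and are not
reproducible here.
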