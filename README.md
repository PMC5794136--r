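# pregepi

Infers **pregnancy episodes** — the interval from estimated last menstrual
period (LMP) to pregnancy outcome — from OMOP-CDM-like event tables
(person, observation_period, condition/procedure/observation/drug
occurrences), for pharmacoepidemiologists who need trimester-resolved drug
exposure but have no recorded gestational age.

## The algorithm

**Step 1 — outcome classification.** Outcome records are assessed per
person in a fixed hierarchy (live birth → stillbirth → ectopic → abortion
→ delivery-only). A candidate at date *d* is accepted iff

* |*d* − *d*ₐ| ≥ S(classₐ, class) for every already-accepted outcome *a*,
  where S is the inter-outcome minimum-spacing table (collapses repeat
  billings of one delivery);
* no antenatal visit / pregnancy confirmation falls in (*d*, *d* + 42]
  (all classes but live birth — screens rule-out diagnoses);
* ectopic only: methotrexate, ectopic surgery or an ectopic-associated
  concept occurs in [*d*, *d* + 14]; the outcome date moves to the last
  treatment date in that window. Abortion dates move to the last abortion
  record within 14 days. Accepted deliveries are re-labelled live births.

**Step 2 — start estimation.** The highest-ranked eligible marker sets the
start: LMP (−0 d) ≻ gestational age record (−weeks×7) ≻ fertility
procedure (−13) ≻ nuchal ultrasound (−89) ≻ AFP screen (−123) ≻ amenorrhea
(−55) ≻ urine test (−55) ≻ outcome-specific average gestation (280 d
full-term live birth, 245 preterm, 196 stillbirth, 70 abortion, 56
ectopic). A marker is eligible iff min_term < outcome − implied_start <
max_term (strict; 161/301 d for live births) and it is not dated before
the prior outcome plus its retry period, to which the start is also
clamped. Low-confidence starts are adjusted against contraceptive and
confirmation records.

Episodes enter the cohort when the person is female, 12–55 years old at
start, continuously enrolled across the episode, and ≥ 2 categorized
pregnancy events fall inside it.

The package also provides the **disproportionality screen** that curates
ectopic-associated concepts (prevalence ratio > 5 in 60-day post-ectopic
windows vs a reference female population), a **synthetic cohort
generator** with planted ground truth and configurable claims noise, and
the characterization / fertility-sensitivity / marker-proximity /
profile-export analytics.

## Worked example

```r
library(pregepi)

coh <- generate_cohort(sim_config(n_persons = 200, seed = 42))
res <- build_episodes(coh, default_concept_sets(), pregepi_config())
nrow(res$episodes)                             # 220 (226 planted; 6 excluded
str(res$report)                                #  by the >=2-event rule)
characterize(res$episodes)$outcome_proportions
```

```
  outcome_class   n        pct
1      abortion  54 24.5454545
2       ectopic   2  0.9090909
3    live_birth 162 73.6363636
4    stillbirth   2  0.9090909
```

The proportions mirror the generator's configured outcome mix (73% live
births, 25% abortions); each episode row carries the outcome date, the
inferred start and the marker that produced it:

```
  person_id outcome_class start_date outcome_date     start_method
1    P00002    live_birth 2010-10-26   2011-07-29       amenorrhea
2    P00003    live_birth 2010-05-12   2011-01-29        fertility
3    P00004      abortion 2010-05-04   2010-07-29       urine_test
4    P00005      abortion 2010-04-09   2010-06-18 outcome_estimate
```

`fertility` means the start is the conception-dating procedure date minus
13 days; `outcome_estimate` means no marker was eligible and the
outcome-specific average gestation was subtracted.

A command-line front end lives in `exec/pregepi`
(`simulate` / `infer` / `characterize` subcommands).

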