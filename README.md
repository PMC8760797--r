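# sepsiscriteria

Rule-based sepsis phenotyping from ICU event streams and temporal agreement
with daily expert labels.

## The problem

Retrospective sepsis research on electronic health records (EHR) usually
*defines* sepsis onset through clinical criteria: Sepsis-1/2 (SIRS in the
context of a suspected infection) or Sepsis-3 (SOFA ≥ 2 in that context).
How well those rule-based onsets agree — in time, not just per patient —
with the diagnosis the treating intensivist actually held at the bedside is
the question this package operationalizes. It implements, as tested,
reusable components:

- **Cohort model** — ICU encounters bounded by
  `start = min(admission, first vital)` / `end = max(discharge, last vital)`,
  a daily 2 PM rating schedule, and the five-category ordinal working
  diagnosis (*neither* < *SIRS* < *sepsis* < *severe sepsis* <
  *septic shock*) with editing-rate accounting.
- **Criteria engine** — carry-forward state reconstruction (every charted
  value persists until replaced), evaluation at every event time or at least
  every 30 min, SIRS as a point determination (≥ 2 of 4 criteria
  concomitantly), and SOFA as the sum of the six subscore maxima over the
  preceding 24 h.
- **Onset detection** — suspicion of infection from temporally paired
  antibiotic and body-fluid-culture orders (antibiotic first ≤ 24 h, culture
  first ≤ 72 h), a 72-h infection window (−48 h to +24 h around the
  suspicion), and Sepsis-1/2 / Sepsis-3 (absolute and ΔSOFA) adjudication at
  onset.
- **Label processing** — day-2 label transfer, on-admission rule,
  absorbing-state encounter category, on-admission vs incident vs
  indeterminate timing, day-to-day transitions, and the validation inclusion
  filter.
- **Agreement statistics** — Krippendorff's α (nominal and ordinal,
  coincidence-matrix form, missing cells allowed) with a bootstrap CI,
  PABAK `(k·Po − 1)/(k − 1)`, 2×2 test performance, and the temporal
  scenario classification: **A** = true negative, **B** = criteria within
  the 24 h before the first sepsis label (timely), **C** = overdue (late or
  absent), **D** = untimely (early by > 24 h, or positive without a label).
- **Synthetic cohort generator** — encounters, ordinal Markov label chains,
  planted order pairs and threshold-crossing observations under a
  configurable detection model (sensitivity, specificity, timeliness), so
  the entire pipeline is testable without patient data.

## Worked example

```r
library(sepsiscriteria)

cfg <- cohort_config(n_encounters = 100, seed = 42)
res <- run_pipeline(config = cfg)

res$report$sepsis12$scenario_counts
#> $A  49   $B  28   $C  10   $D  12

round(unlist(res$report$sepsis12$temporal), 3)
#>              sensitivity              specificity                      ppv
#>                    0.737                    0.803                    0.700
#>                      npv                       po                    pabak
#>                    0.831                    0.778                    0.556
#> positive_class_agreement negative_class_agreement
#>                    0.651                    0.875

res$summary[, 1:5]
#>        category  n percent deaths mortality_percent
#> 1       neither 37      37      2               5.4
#> 2          SIRS 19      19      3              15.8
#> 3        sepsis  7       7      0               0.0
#> 4 severe_sepsis  7       7      0               0.0
#> 5  septic_shock 30      30     16              53.3
```

Reading: of the 99 encounters passing the inclusion filter, 28 had the
criteria-based onset inside the 24 h before the first expert sepsis label
(scenario B). The temporal sensitivity `B/(B+C) = 0.737` exceeds the
positive class agreement `B/(all label-positive) = 0.651` because untimely
(early) detections count against the class agreement but are tabulated as
false positives, not misses. `run_pipeline(..., out_dir = )` writes
`criteria.csv`, `episodes.csv`, `classes.csv`, `report.json`, `summary.csv`
and an `exclusions.jsonl` log.

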