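---
title: "Validating rule-based sepsis criteria against daily expert labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating rule-based sepsis criteria against daily expert labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsiscriteria)
```

## The model

Two operationalizations of sepsis are compared on the same ICU encounters.

The **rule-based side** reconstructs patient state from the charted event
stream by carry-forward: every entry persists until replaced, so state is a
right-continuous step function per variable. On an evaluation grid (every
event time, filled so no gap exceeds 30 min) two criteria are evaluated:

* **SIRS** as a *point determination*: at instant $t$, the number of the four
  classic criteria met concomitantly (temperature > 38 or < 36 °C, heart
  rate > 90/min, respiratory rate > 20/min or PaCO~2~ < 32 mmHg, WBC > 12 or
  < 4 ×10³/mm³ or band forms > 10 %); SIRS is present when ≥ 2 are met.
* **SOFA** as a *rolling summary*: each of the six organ subscores (0–4) is
  the maximum of its pointwise value over the preceding 24 h (truncated at
  the encounter start), and the total is the sum of the six maxima.

Suspicion of infection is detected from order pairing: an antibiotic
administration followed by a body-fluid culture within 24 h, or a culture
followed by an antibiotic within 72 h; the suspicion time is the earlier
event of the earliest qualifying pair. A 72-h **infection window** spans
−48 h to +24 h around it, truncated at the encounter bounds, closed at both
ends. At onset (the suspicion time), *Sepsis-1/2* is met if SIRS is present
anywhere in the window; *Sepsis-3* if the rolling SOFA reaches ≥ 2 there
(absolute mode) or rises by ≥ 2 over its value at the truncated window
start (delta mode).

The **expert side** is a daily 2 PM five-category ordinal working diagnosis
per encounter. The processing rules: a missing day-1 label inherits a
sepsis-spectrum day-2 label (day-2 transfer); the encounter category is the
ordinal maximum over the stay (absorbing state); the first sepsis-spectrum
label is *on-admission* when it is the day-1/day-2 on-admission label with
no preceding non-sepsis label, *incident* when preceded by a non-missing
non-sepsis label, and *indeterminate* otherwise. The validation filter
excludes indeterminate encounters, encounters without any label, and
sepsis-free encounters with more than 2 consecutive missing labels.

**Agreement** is quantified two ways. Dichotomously, "criteria ever met" vs
"sepsis label ever present" gives a 2×2 table with nominal Krippendorff's α
and PABAK. Temporally, each encounter falls in exactly one scenario:
A (neither side positive), B (criteria onset within the closed 24-h interval
before the first label), C (criteria late or absent despite a label),
D (criteria > 24 h early, or positive without a label). The 2×2 mapping is
tp = B, tn = A, fn = C, fp = D; class agreements divide B and A by the
label-positive and label-negative encounter counts.

## Design choices on genuinely open points

* **Scenario-D encounters with a label** (criteria > 24 h early) are counted
  as false positives, not misses. This is the only mapping under which the
  temporal sensitivity B/(B+C) systematically exceeds the positive class
  agreement B/(all label-positive), the ordering such validation studies
  report. The alternative (D with a label → fn) is available via
  `temporal_confusion(untimely_positive = "fn")`.
* **ΔSOFA baseline**: the rise-by-2 variant needs a reference value; we use
  the rolling SOFA at the truncated window start. A running-minimum baseline
  would be more sensitive but is harder to interpret when the window is cut
  at admission; the window-start choice is the conservative reading.
* **Boundary conventions** are closed everywhere: a criteria onset exactly
  at the label instant or exactly 24 h before it is scenario B; an
  antibiotic→culture gap of exactly 24 h qualifies as a pair.
* **Ties in the event stream**: two entries with an identical timestamp are
  resolved by file order — the later row wins — which keeps carry-forward
  deterministic under round-tripping.
* **Missing data** score 0 (SOFA) and "not met" (SIRS); ventilation status
  is an optional 0/1 observation and, when never charted, the respiration
  subscore is capped at 2 since subscores 3–4 require ventilatory support.
* **Re-encounters** are treated as independent encounters; the merging rules
  of administrative transfers are out of scope.
* **Thresholds** (SIRS cut-offs, the six SOFA subscore tables) ship as JSON
  (`inst/extdata/sirs.json`, `sofa.json`) and every function accepts a
  modified table; the defaults are the original consensus values.
* **Interface**: the package's functions plus `run_pipeline()` (which writes
  `criteria.csv`, `episodes.csv`, `classes.csv`, `report.json`,
  `summary.csv`, `exclusions.jsonl`) are the intended entry points; a shell
  wrapper would add nothing over `Rscript -e`.

## What the synthetic generator emulates

`generate_cohort()` draws encounters whose *statistical structure* matches a
one-year surgical-ICU survey: 42.6 % of encounters receive a sepsis-spectrum
label; on-admission and incident sepsis occur 2:1; daily labels evolve as an
ordinal Markov chain with 83 % self-transition; 1.6 % of edited
questionnaires lack the working diagnosis and 92.1 % of rating instants are
edited; lengths of stay and ICU mortality vary by eventual category
(means 3.1–17.2 days, mortality 5.9–39.7 %). Background observations are
drawn near clinically plausible means placed well away from every
threshold; when an encounter is flagged *detected* under the configured
criteria sensitivity/specificity, a qualifying order pair and
threshold-crossing observations (fever + tachycardia for SIRS;
thrombocytopenia + creatinine rise for SOFA, jointly worth 5 points) are
planted inside the infection window, with the onset placed inside the 24 h
before the first label with probability `p_timely_given_detected` and
otherwise early or late. One master seed feeds a per-encounter substream, so
early encounters are byte-stable when `n_encounters` grows.

Two deliberate simplifications matter for interpretation. First, label
chains are clamped so the eventual category equals the planted one; at the
range boundaries this inflates the realized self-transition rate a few
points above the configured 0.83. Second, criteria positivity is planted
*jointly* for SIRS and SOFA, so the Sepsis-1/2 vs Sepsis-3 concordance of
the generator is essentially perfect (α ≈ 1) — an idealization of the very
high (≈ 0.96) concordance such comparisons report, useful as a coupling
check but not a physiological claim. More generally the generator emulates
the data *structure*, not physiology: passing tests show the pipeline's
rules and statistics are implemented correctly, not that real EHR streams
satisfy the planted regularities (no diurnal patterns, no correlated organ
failure, no informative missingness).

## Numerical and degenerate-input choices

* Timestamps are timezone-naive local times at minute resolution (held as
  UTC POSIXct); the 2 PM anchor and all windows are configurable constants.
* Krippendorff's α uses the coincidence-matrix form; each unit with $m \ge 2$
  pairable values contributes each ordered pair with weight $1/(m-1)$;
  ordinal distances are squared cumulative-marginal differences. With zero
  expected disagreement α is reported as `NA` with a warning rather than a
  value. The bootstrap CI resamples units (percentile, default 2000
  resamples, fixed seed) and skips degenerate resamples with a count.
* Empty rating schedules make the editing rate an explicit error; cohorts
  with no sepsis labels yield `NA` sensitivities rather than failures;
  encounters without orders simply produce no infection episode.
* Observations up to 48 h before the encounter start are accepted (they can
  initialize carry-forward state inside an early infection window); earlier
  ones are dropped with a warning.

## Problem sizes

The shipped tests exercise the α implementation against a naive all-pairs
oracle on 200 random instances, the rolling SOFA against a 1-min dense-grid
brute force on 100 random streams, grid sufficiency of SIRS detection on
random streams, scenario totality on an exhaustive offset grid, parameter
recovery on two 500-encounter cohorts (planted sensitivity 0.7, specificity
0.9), and criteria concordance on a 300-encounter cohort; the acceptance
script uses one 761-encounter cohort. These sizes put all binomial checks
inside exact 99 % intervals while keeping a full run in the low minutes on
one core.

## Known limitations

Septic-shock adjudication (vasopressor + lactate), antimicrobial
dose/appropriateness logic, severity scores beyond SIRS/SOFA, imputation
beyond carry-forward, and any mixed-model analysis of SOFA trajectories are
out of scope. The questionnaire's focus-localization and organ-dysfunction
items are carried only as pass-through fields. Indeterminate-timing
handling beyond the stated exclusion, and agreement across a single missing
day when counting transitions (we require strict adjacency), follow the
stricter reading where the source conventions are under-specified.
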