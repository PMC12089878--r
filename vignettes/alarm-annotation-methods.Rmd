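---
title: "Annotating ICU alarms for actionability: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating ICU alarms for actionability: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icualarms)
```

## The annotation model

An ICU monitor alarm is *actionable* when health-care staff react to it:
when an intervention counteracting the physiological deterioration is
documented within a defined post-alarm time window. `icualarms` decides
this retrospectively and deterministically from three tabular sources — the
alarm log (bed, timestamp, one of 14 monitor labels), the respiratory
documentation (airway devices, ventilation device/mode states with standby
flags, set parameter values), and the medication administration record —
linked by bed and timestamp to ICU stays.

The 14 labels cluster into five physiological alarm conditions (PACs).
Saturation labels always mean a low-saturation condition; asystole and
extreme bradycardia a low-heart-rate condition; extreme tachycardia a
high-heart-rate one. The generic heart-rate label and the four invasive
pressure labels alarm on either threshold, so `classify_pac()` takes the
crossed threshold direction from the alarm log for them; the package
accepts the direction in a separate column because monitor exports differ
in where they carry it.

Eight rules decide the label, and each alarm is assessed individually —
co-occurring alarms are not merged, so one intervention may render several
simultaneous alarms actionable. The respiratory rules apply only to the
low-saturation condition and share one template: the last value before the
alarm is compared against the peak value documented in the 30-minute
post-alarm window, with a rule-specific guard.

* **Airway-device change.** Free-text device entries resolve through a
  leveled mapping (1 = no device documented, 9 = endotracheal tube or
  tracheal cannula); the rule fires on a level escalation with no removal
  of the new device logged inside the window. A device is considered in
  place from its documented insertion until a removal timestamp (or a
  newer device) supersedes it.
* **Therapy change.** Ventilation device and mode are always documented
  as a pair; each pair maps to a respiratory-support-therapy category and
  level (1 = spontaneous breathing … 7 = controlled ventilation). Level 0
  exists only at evaluation time: while a ventilator is in standby its
  documented settings do not describe delivered therapy, so the effective
  level is 0 — except for spontaneous breathing and oxygen therapy, where
  standby is legitimate. Escalations documented while standby is active do
  not fire the rule; conversely, leaving standby for any active therapy is
  an escalation from level 0.
* **Parameter increase.** For the six settable parameters (oxygen flow,
  FiO2, PEEP, pressure support, inspiratory pressure, set rate) a raise
  fires the rule, but a value only counts if the parameter is settable
  under the therapy in force at the setting's time, per the 7×7
  compatibility table; incompatible entries (a PEEP value during oxygen
  therapy, say) and entries during non-exempt standby count as 0. Oxygen
  flow is one logical parameter whose flowmeter/non-flowmeter variant is
  chosen by the therapy level (level 2 means flowmeter oxygen therapy).

The five medication rules apply to all PACs over a 15-minute window —
except that stopping or reducing a drug is never counted for the
low-saturation condition. All rules work on one active ingredient at a
time; a drug id resolving to two or more ingredients is a mixture and is
assessed as one unit via a dedicated mixture relevance table. Technique is
bolus iff the start equals the end timestamp. A new continuous episode is
a *start* unless a same-ingredient episode ended within the 5-minute
adjacency gap (then it is an *increase* if the rate rose) or still runs in
parallel; endings are mirrored as *stop*/*decrease*. Rates compare after
unit conversion; across different concentrations the administered dose per
time (rate × concentration) is compared instead, and per-kilogram rates
need a body weight — anything that cannot be brought to a common scale is
*incomparable* and never fires a rate rule. Intravenous fluids below the
carrier threshold are vehicles, not therapy, and are invisible to all
rules.

## Parameters

All constants live in one `annotation_config()` object:

| parameter | default | unit | meaning |
|---|---|---|---|
| `resp_window_min` | 30 | min | post-alarm window for respiratory rules |
| `med_window_min` | 15 | min | post-alarm window for medication rules |
| `med_adjacency_gap_min` | 5 | min | closed gap chaining an ending to a restarting administration |
| `ad_removal_tolerance_min` | 1 | min | a new device documented up to this long before the predecessor's removal is one change |
| `rounding_granularity_min` | 5 | min | grid to which PDMS medication timestamps are rounded down |
| `fluid_carrier_threshold_ml_h` | 500 | mL/h | strictly below: carrier; at or above: fluid therapy |
| `rounding_compensation` | `TRUE` | — | treat grid-aligned medication timestamps as `[t, t+granularity)` |
| `range_bound` | `"compatible"` | — | which range-table bounds remove implausible values |
| `planned_match_tolerance_min` | 30 | min | administration-to-prescription match tolerance |

The windows, gap, tolerance, granularity and fluid threshold are the
method's published operating points; the last three rows are
implementation choices the method leaves open, surfaced as configuration.

## Numerical and boundary choices

* Post-alarm windows are half-open `[t, t + w)`; an event exactly at the
  alarm instant belongs to the window, and "last before" is inclusive at
  `t`. Half-open intervals avoid double counting at boundaries.
* Stay linkage uses half-open admission/discharge intervals; an alarm at a
  discharge instant belongs to the next stay on that bed. Overlapping
  stays on one bed are rejected outright.
* The 500 mL/h fluid threshold is strict for carriers: exactly 500 mL/h is
  therapy.
* The 5-minute adjacency gap is closed at both ends (`[0, 5 min]`) and
  configurable; the boundary convention is not fixed by the method's
  description.
* Parameter comparisons are strict (`last < max`); equal values never
  fire.
* With no prior setting, the last parameter value is 0, so a first
  in-window setting counts as an increase; with no documented ventilation
  state the patient is taken to breathe spontaneously (level 1).
* Unmapped free text (devices, device/mode pairs, drug ids, mixtures,
  units) produces an explicit "unmapped" outcome that keeps the affected
  rule from firing; a batch never halts on vocabulary gaps.
* Rate equality is tested with `all.equal` tolerance to keep unit
  conversion round-trips from fabricating increases.
* Rounding compensation applies to window membership only; adjacency and
  parallelism use raw timestamps. A rate change entered through one PDMS
  dialog carries one timestamp to both the ending and the starting
  administration, so round-down moves the pair together and the adjacency
  gap is unaffected; interval-intersection on the window test is then the
  minimal correction that removes the false negatives caused by
  flooring.
* Tie-breaks: episodes are evaluated in (start, end, order id) order, so
  results are invariant to input row permutations.

## What the generator emulates — and what it does not

`simulate_bundle()` produces stays, alarm logs and PDMS-style tables with
a ground-truth ledger. Alarms sit on an 80-minute slot grid with seconds
jitter: neighbouring alarms' 30-minute windows and the 35-minute pre-alarm
baseline documentation cannot overlap, which is what makes the planted
label provable. Each alarm receives a scenario: a positive variant planting
exactly the documentation that fires one targeted rule, or a negative
variant violating exactly one condition of that rule (device removed inside
the window, change documented under standby, equal rates, carrier-rate
fluid, irrelevant mixture, planned administration, value not compatible
with life, and so on). Defaults — 24-hour stays, 0.75 alarms/hour, 60%
intervention propensity — are plausible ICU magnitudes chosen once for the
test conditions; event timestamps are deliberately kept off the 5-minute
grid so that grid alignment encodes injected rounding, not chance.

`inject_errors()` reproduces three documented PDMS error processes:
deletion of the predecessor removal in a configurable fraction (default
9.0%) of airway-device changes; mis-documentation of ventilation changes
as performed during standby (default rate 53,875/230,711 ≈ 23.4% of
changes at therapy levels 3+), with the delayed deactivation drawn from a
log-normal solved from the two published quantiles (median 7 min, 75th
percentile 20 min — the minimal positive-support choice given two
quantiles); and flooring of a configurable fraction (default 60%) of
distinct medication timestamps to the 5-minute grid.

The generator does **not** emulate vital-sign waveforms (rules never read
them), alarm bursts or co-occurrence structure, free-text spelling noise
beyond the shipped vocabulary, censoring at shift changes, or
interventions documented with the wrong stay. Passing the
ground-truth-recovery and oracle-equivalence tests therefore demonstrates
that the engine implements the rule set exactly — not that the rule set
captures every way real ICU documentation can deviate from what was done
at the bedside.

Test and acceptance problem sizes — bundles of roughly 500–550 alarms over
36 stays for recovery checks, 1,000 random small instances for the
brute-force equivalence check, and ≥10,000 airway-device changes for the
error-rate measurement — were chosen as the smallest sizes at which the
binomial tolerances of the checks are meaningful.

## Mapping content

The shipped mapping tables are synthetic. They carry the exact schema and
category counts of an institutional mapping — 18 airway-device categories
ordered over levels 1–9, 7 respiratory-support-therapy categories over
levels 1–7, 8 administration-route categories, 2 techniques, and the full
7×7 parameter compatibility table — but representative German-flavoured
free-text entries and a small drug list. Institution-specific vocabularies
(the real method mapped over a thousand unique device strings) load
through `load_mappings()` against the same schema, and
`validate_mappings()` / the `validate-mappings` CLI subcommand enforce the
structural invariants before any annotation.

## Known limitations

* Respiratory rules only assess escalations; de-escalation of ventilation
  after an alarm is never an intervention here, and an airway-device
  removal alone does not count.
* Alarm priorities, technical alarms, alarm durations and alarm trends are
  outside the model.
* The stop/decrease exclusion for low-saturation alarms is asymmetric by
  design: sedation stops that resolve desaturations are not captured.
* Labels are documentation-based: an intervention performed but documented
  outside the window (beyond the modeled rounding), or on the wrong stay,
  yields a false negative the method cannot see.
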