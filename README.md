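# icualarms

Rule-based actionability annotation of ICU patient-monitoring alarms.

Most monitor alarms in intensive care are never followed by an
intervention; this nonactionable majority drives alarm fatigue, and no
public ICU dataset records which alarms staff actually reacted to. For an
alarm to be called *actionable*, an intervention counteracting the
physiological deterioration must be documented within a defined time window
after the alarm start. `icualarms` implements a deterministic, scalable
annotation method that links each monitor alarm to respiratory and
medication management interventions documented in PDMS-style (patient data
management system) records, so that large retrospective alarm logs can be
labeled semi-automatically — for alarm-quality projects and as training
labels for machine-learning work. It is written for clinical-informatics
researchers with tabular alarm and PDMS extracts in hand; a seeded
synthetic-data generator with known ground truth makes the whole method
testable without any hospital data.

## The method

Fourteen monitor alarm labels (Desat, SpO2, SpO2l, SpO2r, SpO2po, SpO2pr,
Asystolie, xBrady, xTachy, HF, ABPs, ARTs, ABPm, ARTm) are clustered into
five physiological alarm conditions (PACs): SpO2_low, HR_low, HR_high,
IBP_low, IBP_high. Eight general rules decide actionability; an alarm is
actionable iff at least one applicable rule fires.

**Respiratory rules** (SpO2_low only, window `[t, t + 30 min)`), each of
the form `last(x) < max(x)` plus a guard condition:

| rule | fires when | guard |
|---|---|---|
| `ad_change` | airway-device (AD) level escalates (levels 1 = no AD … 9 = endotracheal tube / tracheal cannula) | no removal of the new device logged in the window |
| `rst_change` | respiratory-support-therapy (RST) level escalates (levels 1–7; 0 = ventilator standby) | changes documented during active standby do not count |
| `param_increase` | a settable parameter (O2 flow, FiO2, PEEP, Psupp, Pinsp, set rate) is raised | the parameter must be settable under the RST in force (compatibility table); incompatible or standby values count as 0 |

**Medication rules** (all PACs; stop/decrease never for SpO2_low; window
`[t, t + 15 min)`), per active ingredient, with a 5-minute adjacency gap
chaining endings to restarts: `med_bolus`, `med_start`, `med_increase`,
`med_stop`, `med_decrease`. Technique is bolus iff start time equals end
time; rates are compared after unit conversion, and across different
concentrations by dose per time (rate × concentration); intravenous fluids
below 500 mL/h are carriers and invisible to the rules; mixtures
(multi-ingredient products) are assessed as one unit.

Preprocessing links alarms to stays by bed and timestamp, removes values
not compatible with life, excludes administrations planned in advance via
prescriptions, and deduplicates documentation. Because PDMS input dialogs
round many medication timestamps down to 5-minute grid points, a
grid-aligned timestamp is treated as the uncertainty interval
`[t, t + 5 min)` when testing window membership (switchable via
`rounding_compensation`).

The bundled mapping tables (airway devices, ventilation device/mode to
therapy, parameter compatibility, medications, mixtures, units) are
**synthetic**: they reproduce the schema, leveled orderings and category
counts of an institutional mapping (18 AD categories, 7 RST categories, 8
route categories, 2 techniques) with representative entries. Supply your
own tables with identical schema via `load_mappings()`.

## Worked example

```r
library(icualarms)

b <- simulate_bundle(n_stays = 3, seed = 42)      # synthetic ICU bundle
ann <- annotate_alarms(b$alarms, b$stays, b$ad_records, b$vent_states,
                       b$vent_params, b$medications, b$prescriptions)
ann
#> <alarm_annotation> 49 alarms: 22 actionable, 27 nonactionable, 0 unlinked

glance(ann)
#> # A tibble: 1 × 5
#>   n_alarms n_actionable n_nonactionable n_unlinked n_rules_fired
#>      <int>        <int>           <int>      <int>         <int>
#> 1       49           22              27          0            22

head(tidy(ann)[, c("alarm_id", "pac", "label", "rule_id", "matched_ref")], 6)
#> # A tibble: 6 × 5
#>   alarm_id pac      label         rule_id      matched_ref
#> 1 A00001   HR_high  actionable    med_decrease med:norepinephrine:OA00001a
#> 2 A00002   IBP_high nonactionable <NA>         <NA>
#> 3 A00003   IBP_high nonactionable <NA>         <NA>
#> 4 A00004   SpO2_low nonactionable <NA>         <NA>
#> 5 A00005   HR_low   actionable    med_increase med:norepinephrine:OA00005b
#> 6 A00006   SpO2_low actionable    ad_change    ad:Tubus
```

One row per fired rule: alarm `A00006` (a desaturation alarm) is
actionable because an endotracheal tube ("Tubus", AD level 9) was
documented inside its 30-minute window; `A00001` (tachycardia) because a
norepinephrine infusion rate was reduced inside its 15-minute window.
Comparing the labels against the generator's ground-truth ledger gives
100% agreement on this clean bundle. `autoplot(ann)` shows labels per PAC,
`plot_rule_counts(ann)` the fired-rule distribution.

A thin command-line wrapper ships in `inst/cli/icualarms`
(`annotate`, `simulate`, `validate-mappings`).

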