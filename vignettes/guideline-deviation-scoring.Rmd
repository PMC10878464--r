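---
title: "Measuring guideline deviations in simulated pediatric cardiac arrest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring guideline deviations in simulated pediatric cardiac arrest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resusdev)
```

## The measurement problem

Pediatric cardiac arrest is rare, time-critical and badly tolerant of
error; deviations from advanced life support guidelines in real events are
associated with worse odds of return of spontaneous circulation.
Simulation studies therefore measure *adherence*: teams run a standardized
nonshockable arrest scenario, raters reconstruct what happened and when,
and deterministic instruments turn that record into scores. `resusdev`
implements that measurement chain end to end on timestamped event logs,
plus the statistical comparison used to contrast teams that did and did
not use a pocket-card cognitive aid.

The package assumes events are instantaneous and timestamped in seconds
from scenario start ($t = 0$), with the scenario length fixed by
configuration (default 600 s, a 10-minute scenario). Two time anchors are
first-class: scenario start (used for reporting times to tasks) and
*recognition of the pulseless state* — the first `pulse_check` event with
an `absent` result — which anchors most checklist windows. All window
comparisons are inclusive: "within 60 s" means elapsed time $\le 60$.
Events exactly at the scenario end are in scope; later events are
validation errors.

## The deviation checklist

The c-DEV15plus score is a 15-item binary checklist for nonshockable
pediatric arrest. Item $i$ contributes 1 (a deviation) when its task is
omitted, late or incorrectly performed, 0 otherwise; the total is the
plain sum, 0 best, 15 worst. Thirteen items are "do" items (timely CPR,
CPR board, 15:2 compression:ventilation ratio, call for help, compressor
switches, EKG monitoring, IV/IO call, two adrenaline calls and two
correct administrations, blood gas, reversible-cause treatment); two are
prohibitions (no shock in a nonshockable rhythm, no non-indicated
medications), which inaction satisfies — an empty log scores 13, not 15.

Items anchored at recognition score as deviations when the pulseless
state was never recognised, and the repeat-adrenaline items (second call
between 180 and 300 s after the first administration, second
administration within 300 s of the first) score as deviations when no
first administration ever happened: the prerequisite chain failed, which
the instrument treats as a performance failure rather than missing data.

Adrenaline quality is the most granular rule: dose within a *strict*
relative tolerance of less than 10% around 0.01 mg/kg
($|d - 0.01w|/0.01w < 0.10$), dilution exactly 0.1 mg/ml (1:10,000),
IV or IO route, a saline flush afterwards, administered while
compressions are ongoing. Exact 10% deviations sit on a floating-point
knife edge and are not part of the contract; tests probe 9% and 10.1%.

### Operationalisations the instrument leaves to the rater

Video raters judge some items holistically; an event-log scorer needs
explicit rules. These are the package's own operational choices, all
exposed as configurable thresholds (`default_thresholds()`) and echoed
into report metadata:

* **15:2 ratio (item 3).** A *cycle* is a maximal run of compressions
  followed by a burst of ventilation events. The item is correct when at
  least 80% of completed cycles have a compression count in [13, 17]
  followed by exactly 2 ventilations. The band and fraction are
  configurable; the defaults tolerate miscounts of ±2 compressions.
* **"Switched more than once" (item 5)** is read literally: at least two
  `switch_compressor` events between the first compression and scenario
  end.
* **"While compressions are being performed" (items 9, 11).** The
  administration instant must fall inside a *compression episode*:
  consecutive compressions whose gaps do not exceed a pause threshold
  (default 2.0 s) merge into one episode. The flush must follow the
  administration within a configurable 30 s.
* **Patient weight** is configuration (default 10 kg — a package default,
  not a clinical constant; set it from the scenario script in use).

## The rubric engine

Technical-skill scores in this literature come from a validated
instrument whose asystole form has seven items totalling 0–13, higher
better. Its item-level definitions are not publicly deposited, so the
package ships a *documented approximation* — seven items covering
recognition, timely CPR, bag-mask ventilation, EKG monitoring, vascular
access, adrenaline administration and correct dosing, with full/partial
credit summing to 13 — behind a config-driven engine (`load_rubric()`)
whose predicates are small declarative specs (`action_present`,
`action_within`, `adrenaline_correct`, `all_of`, `recognized`). Scores
from the default rubric are rubric-engine output, comparable across teams
scored with it, not scores on the original validated instrument; once the
original is transcribed it loads from YAML/JSON and the engine rejects
any rubric whose points do not sum to its declared maximum.

## CPR quality metrics

From the compression stream the package computes, over the resuscitation
period (recognition to scenario end by default; the anchor is selectable
because device conventions vary):

* mean rate = $60 \cdot n_{\text{compressions}} / \text{active episode
  time}$ — pauses degrade the no-flow fraction, not the measured rate;
* mean depth (cm) and the complete-recoil percentage (release residual
  at most 0.5 cm by default);
* no-flow fraction = $1 - \text{active time within period} /
  \text{period length}$, so active and no-flow time conserve the period
  exactly.

Flags use the AHA bands: rate 100–120/min, depth 5–6 cm (the depth band
is implemented in centimetres — the clinically coherent reading of the
50–60 mm recommendation), complete recoil in more than 50% of
compressions, no-flow fraction below 20%.

## Statistics

* **Fisher's exact test** is implemented by full enumeration of all r×2
  tables with the observed margins; the two-sided p-value sums the
  multivariate hypergeometric probabilities of tables no more likely than
  the observed one, with a $1+10^{-7}$ relative guard against
  floating-point ties in the point probabilities. A zero margin returns
  p = 1 by convention, flagged in the method string. An enumeration guard
  (default total ≤ 500) keeps the computation exact and fast.
* **Differences of proportions** are reported in percentage points
  (aid minus no-aid). The exact flavour of "binomial method" CI used in
  the source analyses is not stated, so the CI method is pluggable — Wald
  by default, Newcombe hybrid score available — and always named in the
  output; point estimates, not CI bounds, are what the package asserts
  against published values.
* **Wilcoxon rank-sum** uses the exact distribution when the combined
  sample is at most 25 without ties, otherwise a tie-corrected normal
  approximation with continuity correction; the branch is recorded.
  The **Hodges-Lehmann** estimate is the median of all pairwise
  differences (aid minus no-aid), with a CI from Mann-Whitney inversion.
* **Lin's CCC** uses population (1/n) moments,
  $2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$; it equals Pearson's
  r exactly under equal means and variances and is undefined (an error)
  only when both samples are the same constant. Its CI is a percentile
  bootstrap over case-resampled pairs, 2000 resamples by default, seeded
  and reproducible; the bootstrap errors out if the statistic is
  undefined on more than 10% of resamples rather than silently dropping
  them.
* **Medians and IQRs** use the type-2 quantile rule (inverse empirical
  CDF with averaging, matching the default of the statistical software
  used in the source analyses). The rule is recorded in report metadata.

## The synthetic cohort generator

The generator exists so the full pipeline is testable and demonstrable
without access to recorded scenario data. Its defaults emulate the study
conditions: 27 teams split 14 (no aid) / 13 (aid); per-item conformance
indicators drawn independently per team as Bernoulli variables with the
published per-group correct proportions; times to tasks drawn from
log-normal distributions fitted to published cohort medians and IQRs
(median = $e^\mu$; the IQR maps to $\sigma$ through the normal quartile
0.6745 — positive, right-skewed, the natural family for times to action);
compression rate, depth, recoil and no-flow targets drawn the same way.

The central contract is **generator–scorer consistency**: the emitted
event log, re-scored by the checklist engine, reproduces the drawn
indicators exactly. The builder realises a correct timing item by drawing
the task time from its fitted log-normal *truncated into* the checklist
window, and a deviant one by drawing beyond the window or omitting the
action (omission probability 0.5, configurable); every built record is
re-scored and rebuilt (bounded retries, same indicators) until the round
trip is exact, then the retry budget exhausting is an error rather than a
silently inconsistent record.

Three structural choices keep the construction feasible:

* compressions are never omitted entirely — a late start is the CPR-item
  failure mode — because later items ("during compressions") depend on an
  active stream;
* adrenaline administrations are placed exactly on compression instants,
  so the "not during compressions" failure mode is not generated by
  default (dose, route, flush, timing and omission failures are);
* first-adrenaline omission is only drawn when both repeat-adrenaline
  items are also deviant, since a correct repeat presupposes a first
  administration.

With 15:2 cycles and ~2.5 s ventilation pauses the generated no-flow
fraction has a structural floor near 0.2; drawn targets below it realise
at the floor. Items are independent by default (no latent team-competence
factor), times and items are linked only through the truncation windows,
and rater noise is independent per-item flips — none of which real teams
obey. Passing tests on synthetic cohorts therefore demonstrate the
*scoring and analysis machinery*, not behavioural realism.

### Calibration and problem sizes

Because indicators are exact Bernoulli draws and the round trip is exact,
calibration splits into statistically sound layers, each tested at a size
where its tolerance is comfortably outside sampling noise: indicator
frequencies against the target probabilities within 3 percentage points
at 5,000 draws per group; scored frequencies equal to drawn indicators
(exactly) on moderate cohorts; time-to-task medians within 15% of their
targets on 100 simulated teams. The acceptance-level simulation (modal
cohort median across 200 replicates of 27 teams) runs at the indicator
layer, which the round-trip property proves equivalent to full event-log
simulation for this quantity.

## Degenerate inputs and determinism

Empty event logs score 13 (prohibitions satisfied by inaction); empty
compression streams yield empty episode lists and no CPR-metric rows
while the checklist still scores; a cohort with fewer than two teams in a
group produces descriptives with a warning and no comparison columns;
duplicate team identifiers are an error. Reports are deterministic given
records and seeds — rerunning `run_study()` and `render_report()` with
the same inputs produces byte-identical JSON — and every reported
statistic carries the method (and seed, where stochastic) that produced
it. Serialization round-trips exactly in CSV and JSON; tie order among
simultaneous events is not part of the round-trip contract.

## Known limitations

* The default rubric approximates, and must not be conflated with, the
  validated instrument it stands in for.
* The checklist operationalisations (cycle definition, flush window,
  pause threshold) are reasoned defaults, not validated against video
  raters; sensitivity to them can be explored through the threshold
  configuration.
* The generator's independence assumptions make it a machinery testbed,
  not a behavioural model; no-flow fractions below ~0.2 are not
  reachable under the default cycle structure.
* Shockable-rhythm scenarios, normality diagnostics, multiplicity
  adjustment and regression modelling are out of scope.
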