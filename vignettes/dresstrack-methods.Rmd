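---
title: "Detection rules, evaluation methodology and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection rules, evaluation methodology and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dresstrack)
```

## The detection model

`dresstrack` operates on a stream of fiducial-marker sightings: rows of
`(t, id, x, y, angle)` where positions are normalized camera coordinates
(origin top-left, `x` rightward, `y` downward, both in `[0, 1]`).  That
frame convention is the one used by common fiducial-tracking stacks and is
consistent with the unitless alignment thresholds below.  The orientation
angle is carried in the data model for forward compatibility but is used by
no detection rule.

Each garment region maps to a fixed set of marker IDs (see
`load_layout()`), and each of the nine detection labels is a predicate over
per-marker *visibility runs*:

* A run is an unbroken sequence of sightings with inter-sighting gaps no
  larger than `gap_tolerance_s`.  The default is two frame periods
  (0.133 s at 15 Hz): a camera drops individual frames routinely, and a
  single missing frame should not reset the persistence clock, while two
  consecutive missing frames plausibly mean the marker really left view.
* A region is *qualified* at time `t` when at least one of its markers has
  a run of length ≥ `persist_s` ending within the gap tolerance of `t`.
  The default persistence is 2 s.  A `conservative` preset raises it to
  3 s, a longer debounce that bench testing of live camera pipelines
  has found adequate against spurious back/inside glimpses; 2 s is the
  default because it is the operative value in the garment rule tables
  the engine implements.  Persistence applies uniformly to F/B/I/R/L/A/C — the rule table
  omits the phrase for the shirt-back row only, which we treat as
  typographical, since an undebounced B would fire on exactly the
  transient glimpses the debounce exists to suppress.
* The partial rule `p` uses a longer horizon: one side region must have a
  run ≥ `partial_timeout_s` (default 5 s) while the *opposite* side has had
  no sighting at all for ≥ `partial_timeout_s`.  We read "not visible" as
  complete absence of sightings rather than mere failure to qualify; the
  stricter reading makes `p` an unambiguous one-sidedness signal (a
  sub-persistence glimpse of the other side proves it is dangling in view,
  which should and does suppress `p`).
* The velcro rules compare the most recent positions of markers 208/209
  and 211/212, provided all four have been sighted within the gap
  tolerance: misaligned (`M`) iff any of the four absolute differences
  exceeds its threshold (0.05 vertical, 0.18 horizontal); complete (`C`,
  shirt) iff all four are within threshold *and* all four markers are
  persistence-qualified.  `M` deliberately requires freshness only — it is
  a pure coordinate inequality, and prompting a correction promptly
  matters more than debouncing it.  Pants completion instead requires all
  four upper-front waistband markers individually qualified (the wearer
  must be standing square to the camera).

### Emission semantics

Rules are evaluated at every frame, but events are emitted on *rising
edges*: a label fires at the first frame its rule becomes satisfied, and
can fire again only after the rule has fallen and risen again, with at
least `refractory_s` (default 1 s) between identical labels.  Level
-triggered emission was rejected because a continuously satisfied rule
(e.g. the shirt front, visible throughout a trial) would flood later
phases with repeats.  Under edge semantics, repeated identical detections
still arise — exactly when visibility flickers, which is what live-camera
recordings show — and the partial rule re-arms automatically: after a `p`,
the opposite side must appear (rule falls) and vanish for another timeout
(rule rises) before `p` can fire again, preventing a `p` flood during a
long stall.

At equal timestamps events are ordered by the fixed precedence
`F < B < I < R < L < A < M < p < C`, chosen once for reproducibility; no
ordering of simultaneous detections is otherwise defined.

### Threshold boundary policy

The misalignment rule uses strict `>` and the completion rule `≤`: a
difference exactly equal to its threshold counts as *complete*.  The two
printed inequalities leave the boundary unassigned; assigning it to
completion eliminates the dead zone, and prompting a correction on an
exactly-threshold reading is the worse failure mode.  Comparisons are raw
double comparisons with no epsilon; the test grid therefore constructs
differences that are exact in binary (one member of each pair at the
origin) rather than values like `0.45 − 0.40`, whose representation error
would straddle the boundary.

## Evaluation methodology

A trial's event sequence is segmented into six dressing phases by event
milestones: phase 1 is everything before the first side event (R or L),
phase 2 that event, phase 3 the strict interior until the first
opposite-side event, phase 4 that event, phase 5 the interior until the
first subsequent C, and phase 6 the first C onward.  The phases are
defined narratively in study protocols; this milestone formalization is
the only segmentation computable from the event stream alone, and missing
milestones simply leave later phases empty.

Each of the nine conditions (five shirt, four pants — misalignment is a
velcro error and hence shirt-only) has a per-phase expectation row:
*required* entries are alternative sets (either member of `{R, L}`
satisfies phase 2), *optional* entries are plausible detections that count
neither way (e.g. back/inside glimpses while the garment is handled).
Scoring charges one *missed* per unmet required set and one *unexpected*
per label observed outside the allowed sets.  A label repeated within one
phase counts once — toward requirement or as unexpected — and the extra
occurrences are tallied in a separate `repeats` diagnostic, mirroring how
repeated-detection runs are reported separately in the study methodology.
For the misaligned-shirt condition the acted error makes `M` required in
phase 5; for every other shirt condition `M` is optional there.

`enumerate_trials()` reproduces the randomized complete block design (every
participant × every condition × 2 repetitions, shuffled within
participant), and `aggregate_scores()` accepts an exclusion list so trials
lost to recording failure can be removed before aggregation; under the
reference design with two lost recordings per garment, 108 shirt and 86
pants trials remain, each expecting two limb-worn detections — 388 in
total.

## The scenario simulator

`simulate_trial()` generates streams from piecewise region exposures: a
region is "presented to the camera" for an interval, expressed as
fractions of its phase so scripts scale with phase durations and with
`dressing_speed`.  Marker positions are anchor points plus a seeded,
reflected random walk of amplitude ±0.01 — small enough never to cross the
0.05 alignment threshold from the scripted geometry (aligned velcro pairs
sit 0.05 apart in x and 0.02 in y; the misaligned script offsets the left
members by 0.10 in y).  It does **not** model body kinematics, marker
pose, or image formation: the engine consumes visibility and velcro
coordinates only, so that is what the simulator scripts.

Scripted details worth knowing:

* Non-partial shirt scripts include sub-persistence (< 2 s) glimpses of
  the dangling left front every < 5 s while the right side is donned.  A
  camera facing a held-open shirt does see the far side intermittently,
  and without these glimpses the 5-s partial rule would fire during every
  ordinary transition.
* The shirt-partial script is genuinely one-sided for > 5 s, so `p` fires
  in phase 3, where the expectation row requires it.
* The pants-partial script keeps one leg exposed (in total) far longer
  than the timeout, but the dangling second pant leg is glimpsed
  sub-persistence every < 5 s, so `p` never completes.  This matches both
  the pants expectation rows (which contain no `p`) and how such
  systems behave on live hardware, where folding while pants are
  partially worn defeats partial detection.  The worn side's visibility
  is otherwise continuous, so no spurious second `R`/`L` edges occur.
* Every trial ends with a terminal hold (default 3 s, the "DONE 1 2 3"
  stillness) during which the completion geometry is stable; phase 6 never
  shrinks below the hold even at high dressing speed.  Consequently
  too-fast donning (`dressing_speed` ≳ 3) loses the phase-limited error
  exposures (back/inside) rather than completion.

The noise model has three independent processes: per-frame dropout
`min(1, base + coeff × distance)` (markers are effectively smaller at
distance), transient wrong-region glimpses during transition phases 3 and
5 (Poisson arrivals, exponential durations), and whole-region fold
occlusion per phase.  No quantitative noise rates are available from live
recordings, so the defaults (5 % dropout, 0.10 distance coefficient,
0.05 Hz glimpses of mean 0.5 s, 2 % fold occlusion) were chosen once as
plausible mild-noise values and nothing downstream depends on them; all
acceptance checks run either noise-free or on an explicit dropout grid.
Under the dropout grid the missed-completion rate saturates quickly —
completion requires four simultaneous unbroken 2-s runs, so even 20 %
frame dropout almost always defeats it — which is consistent with
completion being the most fragile detection on live hardware.

Randomness discipline: one master seed; per-trial seeds are
`master + trial index`; every simulator and roster function saves and
restores the caller's RNG state.

## The session state machine

`session_step()` is a pure transition function over abstract hardware
events (presence, drawer open/close, RFID removal, detections, stress
samples).  Design choices where the narrative description leaves room:

* Stress is an abstract unitless level (the skin-conductance hardware is
  out of scope).  Thresholds default to 0.5 (start a soothing activity)
  and 0.8 (notify the caregiver), with the episode algebra: soothe once
  per episode on reaching the soothe level, notify once per episode on a
  later sample strictly above the alert level, reset when stress falls
  below the soothe level.
* `stall_s` defaults to 10 s and `max_corrections` to 3 — "multiple
  attempts" is not quantified anywhere, so these are configuration.
* Prompts are catalog IDs, not text, supporting recorded-voice
  customization; audio is out of scope.  Prompt IDs carry a class
  (`navigation`, `corrective`, `progress`); independent mode emits no
  `progress` prompts, which is exactly the praise/narration suppression
  that distinguishes the modes, while corrective and navigation prompts
  are mode-invariant.
* Drawer lights are represented by the single green (active) drawer index;
  all other drawers are red, so light exclusivity holds by construction.

## Problem sizes and what passing tests show

The suite exercises: a 1296-point boundary-inclusive grid for the
alignment rules; 200 random 1000-frame streams for equivalence between the
incremental engine and a brute-force oracle that recomputes all visibility
runs globally per frame; 100 seeds per dropout level for the degradation
curve; full 198-trial study simulations; and fuzzed session logs for the
determinism and mode properties.  These sizes give stable pass/fail
behavior at interactive runtimes and are stated here as the package's
chosen operating points.

Passing them shows the symbolic layer is correct *given* the simulator's
assumptions.  It does not validate marker recognition itself, human
kinematics, real occlusion statistics, garment-specific marker placement,
or behavior of wearers — the simulator reproduces the catalogued failure
modes qualitatively, not measured rates.  Multi-garment simultaneous
tracking and marker-pose reasoning are explicitly out of scope, and a
pants "front" label is not implemented (the pants rule set defines none).
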