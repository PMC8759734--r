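---
title: "Preferred-range selection of treatment alternatives: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preferred-range selection of treatment alternatives: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefrange)
```

## The decision problem

Choosing an exercise therapy modality for a patient with knee osteoarthritis
is a multi-criteria problem over a *finite* list of alternatives: each
candidate intervention, extracted from a randomized controlled trial arm, is
described by five conflicting objectives,

* $f_1$: patient-facing **cost** of the therapy (EUR) — minimize;
* $f_2$: **net pain change** (%) on the standardized WOMAC pain subscale — maximize;
* $f_3$: **net function change** (%) on the standardized WOMAC function subscale — maximize;
* $f_4$: number of **supervised training sessions** — minimize;
* $f_5$: **length of the treatment period** (weeks) — minimize;

subject to exactly one therapy being selected from the list. Supervision
improves outcomes but raises cost and burden, so no alternative is best on
all five axes; the method's job is to surface a small set of genuine
compromises that match a clinician's stated preferences for a particular
patient, iteration by iteration, until one is prescribed.

`prefrange` implements this as a reusable engine: a data model and parser
for evidence tables (`read_alternatives()`), the optimization core
(`pareto_front()`, `classify()`, `select_compromises()`), an interactive
session loop with a scriptable simulated decision-maker
(`start_session()`, `run_iteration()`, `simulated_dm()`), a session-fee
cost model (`estimate_cost()`), and parallel-coordinate reporting
(`parallel_coordinates_plot()`).

## Objective values from trial summaries

Only arm-level means are assumed available. For each WOMAC subscale the
within-arm change is `pre_mean - post_mean` (lower WOMAC is better, so
positive change is improvement), and the **net change** is the exercise
arm's change minus the control arm's change (`net_change()`), crediting the
intervention only with improvement beyond usual care. Trials reporting
WOMAC on other ranges are first mapped linearly onto the standardized
subscale ranges — 0–20 for pain, 0–68 for function
(`standardize_womac()`, `womac_standard_scale()`); the map sends endpoints
exactly to endpoints and preserves order.

Net changes enter the optimization as percentages. The denominator of that
percentage is a genuine modelling choice — the package uses the **exercise
arm's baseline (pre-intervention) mean on the standardized scale**, the
most common convention for relative improvement; `percent_net_change()`
takes the reference explicitly, so a scale-maximum or control-baseline
convention is equally callable. Variance propagation is deliberately out of
scope: without individual-level data, net changes in variances are not
identifiable, so the engine works with means only.

## The cost model

Cost is the patient's side of the price, accumulated over the measurement
window (baseline to outcome endpoint; later follow-ups excluded): number
and length of supervised sessions, individually or in groups of five,
unsupervised facility or home sessions, check-in calls/messages, and
equipment. The packaged default schedule (`default_fee_schedule()`, early-2021
Finnish price level) charges 100/75/50 EUR for individual supervised
sessions of 60/45/30 minutes, one fifth of that in groups of five, a flat
10 EUR per unsupervised facility session, nothing for home sessions,
10 EUR per contact, and no equipment fee. `estimate_cost()` is an exact
itemized sum — additive over plans and monotone in added items — and
durations are matched exactly against the listed entries: the schedule is
a discrete tariff, so unlisted durations are an error the caller resolves
by rounding to a listed session length, not something to interpolate.
Other countries/years supply their own `fee_schedule()`.

## The optimization core

**Dominance and the candidate pool.** Alternative $a$ dominates $b$ when it
is at least as good on every objective (respecting direction) and strictly
better on at least one. By default every selection draws its candidates
from the Pareto front of the *full* alternative set, computed before
classification, so everything shown to the decision-maker is a genuine
compromise; `restrict_to_front = FALSE` admits dominated alternatives for
exploratory use. Ideal and nadir (best and worst observed value per
objective) are likewise computed over the full set — they are shown to the
decision-maker before any filtering, and they normalize all scores below.

**Preferred ranges.** For each objective the decision-maker states a range
$[l_j, u_j]$ in natural units. The bound on the objective's *bad* side
($u_j$ for minimized, $l_j$ for maximized objectives) is the binding
**reservation** bound; the good-side bound is an **aspiration**. This
asymmetry is forced by the rule that values *better* than desired still
satisfy the range: an alternative cheaper than the stated minimum budget is
not penalized. `range_status()` accordingly returns `within`, `better`, or
`worse` per objective.

**Groups I and II.** An alternative is **group I** when no objective is
`worse`; otherwise **group II**. Group II members are still shown (shaded)
to teach the decision-maker what trade-offs the evidence base actually
offers.

**Closeness.** Group II candidates are ranked by
$$c(x) = \sum_{j=1}^{5} \frac{v_j(x)}{|\mathrm{nadir}_j - \mathrm{ideal}_j|},$$
where $v_j(x)$ is the distance from $x_j$ to the nearest
group-I-eligible value on objective $j$ (zero when the range is satisfied).
The L1 form was chosen because it is simple, monotone in every violation,
and zero exactly on group I; it is isolated behind `closeness_score()` so a
Chebyshev/max scalarization can be swapped in without touching
classification semantics. When an objective is degenerate (all records
equal, ideal = nadir) its normalizer falls back to 1; such an axis can
never create a ranking differential.

**Ranking within group I.** When more group I members exist than slots,
they are ordered by ideal–nadir-normalized L1 distance to the *aspiration
corner* (the vector of good-side bounds), so the alternatives that look
most like the stated wish surface first. The worked example never has more
group I members than slots, so this rule is unconstrained by it; the
absolute-distance form keeps the ranking a proper distance and is the
package's own choice.

**Selection.** `select_compromises(set, prefs, k)` returns the `k` best:
all group I (aspiration-ranked) first, then group II in ascending
closeness. Every ordering breaks ties lexicographically by `(score, id)`,
which makes selections deterministic, replayable, and invariant under row
permutation of the input — properties the test suite checks explicitly.

## The interactive loop

A session fixes `k` once at the start (the number of compromises shown per
iteration; changing it means a new session) and exposes the ideal/nadir
table for orientation. Each iteration takes a complete preference set,
delegates to the selection core, and appends an immutable result to the
history; the decision-maker either supplies new ranges or prescribes one of
the *latest* shown alternatives — choosing a shaded group II therapy is
allowed, since accepting a trade-off is a legitimate outcome, but an
alternative never shown is not. Sessions export as JSON-lines logs
(preferences, selected ids, groups, scores per iteration, plus a dataset
digest) and `replay_log()` re-runs a log to verify bit-identical
selections, the package's reproducibility contract.

`simulated_dm()` makes the loop testable end to end: a policy scripts the
preference sequence, a stop rule (e.g. "stop once at least three shown
therapies satisfy everything") and a choice rule (e.g. "largest function
improvement among shown"). On the packaged scenario it reproduces the
expected two-iteration pattern: one fully satisfying therapy in iteration
1, three in iteration 2, with the mixed resistance+aerobic arm prescribed.

## Visualization

`parallel_coordinates_plot()` draws one polyline per shown alternative
across the five axes. Each axis spans the observed ideal–nadir range and is
oriented (by default) so *better points up*, inverting minimized
objectives — this makes group I lines visually dominant; the orientation is
configurable since conventions differ. Group I lines are opaque and
colored, group II lines translucent grey, and the preferred range appears
as a band on each axis. Because pixel comparison is brittle, the renderer
exposes a `draw_manifest()` — polyline counts, styles, vertex coordinates,
axis endpoints, band extents — which is what the tests assert on.

## The synthetic generator and the scenario fixture

The real evidence table behind the worked example (31 intervention arms
from 21 trials) ships with its source publication's supplement, not with
this package. Two synthetic stand-ins keep every module testable:

* `generate_alternatives(synth_config())` emulates the *structure* of such
  an evidence base: by default 31 arms spread over 21 synthetic studies,
  costs 0–1500 EUR, net efficacy −5–45%, 0–40 supervised sessions, 8–52
  week periods (8 matching the smallest observed period in the worked
  example). A latent resource-intensity driver couples cost and sessions
  to both efficacy objectives with weight `tradeoff_strength` (default
  0.6) plus independent uniform variation and Gaussian noise (default SD
  4 percentage points), so cheap-but-modest and costly-but-effective arms
  genuinely conflict and neither extreme dominates. Sessions and weeks are
  integers; values are clipped to their ranges; generation is a pure
  function of the config including its seed.
* `scenario_dataset()` is a hand-built, fixed set of eight mutually
  nondominated synthetic arms engineered so the two packaged preference
  sets reproduce the worked example's iteration pattern (one group I
  therapy, then three, with the mixed resistance+aerobic arm the final
  choice). Its values are labelled synthetic everywhere; substituting a
  user-supplied copy of the real table via `read_alternatives()` upgrades
  any analysis from pattern-level to exact.

What passing tests on these fixtures shows is that the *method* behaves as
specified — classification semantics, ranking, determinism, the iteration
pattern. What they cannot show is agreement with the real table's values:
clinical heterogeneity, real cost compositions, and the actual magnitude of
net changes are properties of the data, not the engine.

## Numerical choices and degenerate inputs

* Bounds of preferred ranges are inclusive on both sides.
* Ties everywhere break by `(score, id)`; ids are unique by construction.
* Duplicate objective vectors do not dominate each other; all survive
  Pareto filtering.
* A degenerate objective's normalizer falls back to 1 (see above).
* Empty alternative sets are rejected at session start and by the core
  operations; `k` must be a positive integer and selections truncate to
  the pool size.
* Costs are exact sums of tariff entries — no floating-point rounding is
  introduced beyond the inputs themselves.

## Test problem sizes

The property suite exercises the core at the sizes it is meant for:
nondominated filtering is cross-checked against an independent all-pairs
dominance scan on 100 random sets of up to 500 alternatives; reservation
relaxation monotonicity on 1000 random (set, preferences, relaxation)
triples; selection determinism under row permutation, closeness/group
equivalence, and session replay equality on hundreds of seeded cases.
These sizes comfortably bracket realistic evidence bases (tens of arms).

## Known limitations

* Arm-level means only: no variance propagation, no individual-level
  tailoring beyond the preference mechanism itself.
* The closeness and aspiration-ranking scalarizations are reasonable,
  documented choices; other monotone aggregations are defensible and the
  code keeps them pluggable.
* The engine ranks what it is given: instrument conversion (e.g. KOOS to
  WOMAC), guideline-based pre-filtering, and group decision-making are
  upstream or downstream of it by design.
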