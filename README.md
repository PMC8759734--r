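# prefrange

Interactive preferred-range multiobjective selection of treatment
alternatives, demonstrated on exercise therapy modalities for knee
osteoarthritis (OA).

Clinicians choosing an exercise therapy for a knee-OA patient face a finite
list of evidence-backed interventions that conflict on several axes at
once: supervised programmes tend to help more but cost more and demand more
sessions. `prefrange` is a decision-support engine for exactly this
situation. Each alternative is scored on five objectives,

| objective | direction | units |
|---|---|---|
| cost of therapy `f1` | minimize | EUR |
| net pain change `f2` (standardized WOMAC pain, 0–20) | maximize | % |
| net function change `f3` (standardized WOMAC function, 0–68) | maximize | % |
| supervised training sessions `f4` | minimize | count |
| treatment period `f5` | minimize | weeks |

subject to choosing one therapy from the list. Net change means the
exercise arm's mean improvement minus the control arm's. Instead of a
single "best" answer, the engine supports an interactive loop: the
decision-maker states a **preferred range** `[l, u]` per objective, and
each iteration shows the `k` best compromises from the Pareto front —
**group I** alternatives satisfy every range (values *better* than desired
still count), **group II** alternatives violate some ranges and are ranked
by an ideal–nadir-normalized L1 closeness score

```
c(x) = Σ_j  violation_j(x) / |nadir_j − ideal_j|,
```

which is zero exactly on group I. Preferences are revised until the
decision-maker prescribes one of the shown therapies. A session-fee cost
model, WOMAC scale standardization, a seeded synthetic evidence-base
generator, parallel-coordinate plots, and a scriptable simulated
decision-maker round out the toolkit.

## Worked example

The packaged `scenario_dataset()` holds eight synthetic intervention arms
engineered to exhibit the canonical two-iteration pattern (real evidence
tables load through `read_alternatives()`; see below).

```r
library(prefrange)

set <- scenario_dataset()
ideal_nadir(set)
#>   objective               direction units    ideal nadir
#> 1 cost_eur                minimize  EUR          0  1500
#> 2 pain_net_change_pct     maximize  %           28     8
#> 3 function_net_change_pct maximize  %           45     6
#> 4 supervised_sessions     minimize  sessions     0    36
#> 5 period_weeks            minimize  weeks       10    52
```

The best/worst table orients the decision-maker. Iteration 1 asks for a
therapy costing 300–600 EUR, improving pain by 15–30% and function by
15–25%, with at most 15 supervised sessions over 8–26 weeks:

```r
prefs <- example_preferences()
s <- start_session(set, k = 4)
run_iteration(s, prefs$iteration1)
#> <compromise_selection> 4 shown (k = 4): 1 group I, 3 group II
#>   id                   group closeness aspiration_dist
#> 1 cheung-yoga          I         0                1.34
#> 2 braghin-strength     II        0.139            1.44
#> 3 krasilshchikov-mixed II        0.25             1.62
#> 4 aquatic-group        II        0.3              2.08
```

Only the yoga-style arm satisfies every range; three near-miss compromises
are shown shaded. Wanting more function improvement and accepting more
supervised sessions, the decision-maker relaxes `f4` to 30 sessions,
raises the function aspiration to +40% and tightens the budget to 200–500
EUR:

```r
run_iteration(s, prefs$iteration2)
#> <compromise_selection> 4 shown (k = 4): 3 group I, 1 group II
#>   id                   group closeness aspiration_dist
#> 1 krasilshchikov-mixed I        0                 1.05
#> 2 braghin-strength     I        0                 1.54
#> 3 lin-taichi           I        0                 1.88
#> 4 cheung-yoga          II       0.0333            1.54

finish_session(s, "krasilshchikov-mixed")
s
#> <therapy_session> 8 alternatives, k = 4, 2 iteration(s), state: finished
#> chosen: krasilshchikov-mixed
```

Three therapies now satisfy everything; the mixed resistance+aerobic arm
leads (closest to the aspiration corner, with the largest function gain,
+38%) and is prescribed. `parallel_coordinates_plot(run_iteration(...))`
renders the iteration as a parallel-coordinate figure with group I
highlighted, group II shaded, and the preferred ranges drawn as bands.

Costing a plan against the packaged fee schedule:

```r
plan <- intervention_plan(
  data.frame(setting = c("supervised_group5", "unsupervised_home"),
             duration_min = c(60, NA), count = c(12, 24)),
  contacts = 2)
estimate_cost(plan)
#> [1] 260    # 12×20 EUR group sessions + 24 free home sessions + 2×10 EUR contacts
```

## Using your own evidence table

`read_alternatives("table.csv")` expects columns `id, study,
exercise_type, cost_eur, pain_net_change_pct, function_net_change_pct,
supervised_sessions, period_weeks` (plus optional arm sizes); differently
named columns are remapped via a dialect, e.g.
`read_alternatives("table.csv", dialect = c(cost_eur = "price"))`. Helpers
`standardize_womac()`, `mean_change()`, `net_change()` and
`percent_net_change()` turn raw WOMAC arm summaries into the objective
columns. A thin command-line front end ships in `inst/cli/prefrange`
(`ranges`, `iterate`, `session`, `replay`, `cost`, `synth` subcommands).

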