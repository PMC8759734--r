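Package: prefrange
Title: Interactive Preferred-Range Multiobjective Selection of Treatment Alternatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support engine for choosing among discrete treatment
    alternatives characterized by several conflicting objectives, demonstrated
    on exercise therapy modalities for knee osteoarthritis. Implements a
    five-objective formulation (therapy cost, net pain change, net physical
    function change, number of supervised sessions, treatment length), Pareto
    dominance filtering on finite alternative sets, preferred-range
    (reservation/aspiration) classification of alternatives into fully
    satisfying (group I) and partially satisfying (group II) sets, closeness
    scoring, top-k compromise selection, an interactive session loop with a
    scriptable simulated decision-maker, a session-fee cost model, WOMAC scale
    standardization, a seeded synthetic dataset generator, and
    parallel-coordinate visualization of each iteration's compromises.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ggplot2,
    tibble,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
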