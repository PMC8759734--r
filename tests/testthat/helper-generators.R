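# shared generators and independent oracles for property-style tests

canonical_specs <- canonical_objectives()

# random alternative set on the five canonical objectives
random_set <- function(n) {
  alternative_set(tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    study = sprintf("Study %d", seq_len(n)),
    exercise_type = sample(c("aerobic", "resistance", "yoga"), n, replace = TRUE),
    cost_eur = round(stats::runif(n, 0, 1500), 1),
    pain_net_change_pct = round(stats::runif(n, -10, 50), 1),
    function_net_change_pct = round(stats::runif(n, -10, 50), 1),
    supervised_sessions = sample(0:40, n, replace = TRUE),
    period_weeks = sample(4:52, n, replace = TRUE)
  ))
}

# random complete preference set over the observed ranges
random_prefs <- function(set) {
  rng <- ideal_nadir(set)
  preference_set(lapply(rng$objective, function(k) {
    r <- rng[rng$objective == k, ]
    lo <- min(r$ideal, r$nadir); hi <- max(r$ideal, r$nadir)
    a <- stats::runif(1, lo, hi); b <- stats::runif(1, lo, hi)
    preferred_range(k, min(a, b), max(a, b))
  }))
}

# independent brute-force oracle: full all-pairs dominance scan built from
# outer() comparisons, a different code path from pareto_front()
oracle_front <- function(set) {
  m <- set$records[, names(canonical_specs)]
  dirs <- vapply(canonical_specs, `[[`, "", "direction")
  for (k in names(m)) if (dirs[[k]] == "maximize") m[[k]] <- -m[[k]]
  n <- nrow(m)
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (k in names(m)) {
    le <- le & outer(m[[k]], m[[k]], "<=")
    lt <- lt | outer(m[[k]], m[[k]], "<")
  }
  dom <- le & lt           # dom[j, i]: j dominates i
  set$records$id[!apply(dom, 2, any)]
}

# direct group-I oracle: bound comparisons only, no classify() machinery
oracle_group1 <- function(set, prefs) {
  r <- set$records
  ok <- r$cost_eur <= prefs$cost_eur$upper &
    r$pain_net_change_pct >= prefs$pain_net_change_pct$lower &
    r$function_net_change_pct >= prefs$function_net_change_pct$lower &
    r$supervised_sessions <= prefs$supervised_sessions$upper &
    r$period_weeks <= prefs$period_weeks$upper
  r$id[ok]
}
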