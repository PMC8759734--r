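specs <- canonical_objectives()

test_that("pareto_front agrees with the all-pairs oracle on random sets", {
  withr::with_seed(7, {
    for (i in 1:30) {
      set <- random_set(sample(2:120, 1))
      expect_equal(pareto_front(set), oracle_front(set))
    }
  })
})

test_that("the all-pairs oracle itself matches pairwise dominates() on tiny sets", {
  withr::with_seed(8, {
    for (i in 1:10) {
      set <- random_set(8)
      m <- set$records
      slow <- m$id[vapply(seq_len(nrow(m)), function(j) {
        !any(vapply(seq_len(nrow(m)), function(l) {
          l != j && dominates(m[l, ], m[j, ], specs)
        }, logical(1)))
      }, logical(1))]
      expect_equal(oracle_front(set), slow)
    }
  })
})

test_that("dominance is irreflexive, antisymmetric, and transitive", {
  withr::with_seed(9, {
    for (i in 1:200) {
      set <- random_set(3)
      r <- set$records
      a <- r[1, ]; b <- r[2, ]; c <- r[3, ]
      expect_false(dominates(a, a, specs))
      if (dominates(a, b, specs)) expect_false(dominates(b, a, specs))
      if (dominates(a, b, specs) && dominates(b, c, specs)) {
        expect_true(dominates(a, c, specs))
      }
    }
  })
})

relax_reservation <- function(prefs, key, direction, amount) {
  r <- prefs[[key]]
  new <- if (direction == "minimize") {
    preferred_range(key, r$lower, r$upper + amount)  # raise binding upper bound
  } else {
    preferred_range(key, max(r$lower - amount, -1e9), r$upper) # lower binding lower bound
  }
  prefs[[key]] <- new
  preference_set(unclass(prefs))
}

test_that("relaxing a reservation bound never shrinks group I", {
  withr::with_seed(10, {
    for (i in 1:300) {
      set <- random_set(sample(5:25, 1))
      prefs <- random_prefs(set)
      norm <- ideal_nadir(set)
      before <- vapply(seq_len(nrow(set$records)), function(j) {
        classify(set$records[j, ], prefs, specs, norm)$group
      }, character(1))
      key <- sample(names(specs), 1)
      relaxed <- relax_reservation(prefs, key, specs[[key]]$direction,
                                   stats::runif(1, 0, 500))
      after <- vapply(seq_len(nrow(set$records)), function(j) {
        classify(set$records[j, ], relaxed, specs, norm)$group
      }, character(1))
      expect_true(all(after[before == "I"] == "I"))
      expect_gte(sum(after == "I"), sum(before == "I"))
    }
  })
})

test_that("closeness is zero exactly for group I on random inputs", {
  withr::with_seed(12, {
    for (i in 1:100) {
      set <- random_set(sample(3:20, 1))
      prefs <- random_prefs(set)
      norm <- ideal_nadir(set)
      for (j in seq_len(nrow(set$records))) {
        cl <- classify(set$records[j, ], prefs, specs, norm)
        expect_equal(cl$closeness == 0, cl$group == "I")
        expect_gte(cl$closeness, 0)
      }
    }
  })
})

test_that("selection is invariant under row permutation of the input", {
  withr::with_seed(13, {
    for (i in 1:30) {
      set <- random_set(sample(5:40, 1))
      prefs <- random_prefs(set)
      k <- sample(1:6, 1)
      base <- select_compromises(set, prefs, k)
      perm <- alternative_set(set$records[sample(nrow(set$records)), ], set$specs)
      shuffled <- select_compromises(perm, prefs, k)
      expect_equal(shuffled$selection$id, base$selection$id)
      expect_equal(shuffled$selection$group, base$selection$group)
      expect_equal(shuffled$selection$closeness, base$selection$closeness)
    }
  })
})

test_that("status and classification are invariant under positive rescaling", {
  # rescaling an objective's values, range, and ideal/nadir together must not
  # change any status, group, or closeness contribution pattern
  withr::with_seed(14, {
    for (i in 1:50) {
      set <- random_set(10)
      prefs <- random_prefs(set)
      norm <- ideal_nadir(set)
      key <- "cost_eur"
      a <- stats::runif(1, 0.1, 10); b <- stats::runif(1, -100, 100)
      scaled_records <- set$records
      scaled_records[[key]] <- pmax(a * scaled_records[[key]] + b, 0)
      # keep the affine map exact: drop the clamp when it would bite
      if (any(a * set$records[[key]] + b < 0)) next
      scaled_set <- alternative_set(scaled_records, set$specs)
      scaled_prefs <- prefs
      scaled_prefs[[key]] <- preferred_range(key, a * prefs[[key]]$lower + b,
                                             a * prefs[[key]]$upper + b)
      scaled_prefs <- preference_set(unclass(scaled_prefs))
      scaled_norm <- ideal_nadir(scaled_set)
      for (j in seq_len(nrow(set$records))) {
        cl0 <- classify(set$records[j, ], prefs, specs, norm)
        cl1 <- classify(scaled_set$records[j, ], scaled_prefs, specs, scaled_norm)
        expect_equal(cl1$status, cl0$status)
        expect_equal(cl1$group, cl0$group)
        expect_equal(cl1$closeness, cl0$closeness, tolerance = 1e-10)
      }
    }
  })
})

test_that("a degenerate objective can never produce a violation differential", {
  recs <- random_set(6)$records
  recs$period_weeks <- 12 # all equal: ideal == nadir
  set <- alternative_set(recs)
  norm <- ideal_nadir(set)
  prefs <- preference_set(
    preferred_range("cost_eur", 0, 2000),
    preferred_range("pain_net_change_pct", -100, 100),
    preferred_range("function_net_change_pct", -100, 100),
    preferred_range("supervised_sessions", 0, 100),
    preferred_range("period_weeks", 5, 8) # every record exceeds the cap by 4
  )
  scores <- vapply(seq_len(nrow(recs)), function(j) {
    closeness_score(set$records[j, ], prefs, set$specs, norm)
  }, numeric(1))
  # normalizer falls back to 1: everyone violates equally, no differential
  expect_equal(scores, rep(4, 6))
})

test_that("generated sets are deterministic, in range, and genuinely conflicting", {
  cfg <- synth_config(n = 31, seed = 42)
  a <- generate_alternatives(cfg)
  b <- generate_alternatives(cfg)
  expect_equal(a$records, b$records)
  expect_equal(a$records$id[1], "synth-001")
  expect_equal(nrow(a$records), 31)
  expect_equal(length(unique(a$records$study)), 21)
  expect_true(all(a$records$cost_eur >= 0 & a$records$cost_eur <= 1500))
  expect_true(all(a$records$supervised_sessions ==
                    round(a$records$supervised_sessions)))
  expect_true(all(a$records$period_weeks >= 8 & a$records$period_weeks <= 52))

  # full coupling, no noise: cost order equals efficacy order exactly
  pure <- generate_alternatives(synth_config(n = 20, seed = 3,
                                             tradeoff_strength = 1, noise_sd = 0))
  expect_equal(cor(pure$records$cost_eur, pure$records$pain_net_change_pct,
                   method = "spearman"), 1)

  # singleton is trivially its own front
  one <- generate_alternatives(synth_config(n = 1, seed = 5))
  expect_equal(pareto_front(one), "synth-001")

  # under the default trade-off the front retains competition
  fronts <- vapply(1:10, function(s) {
    length(pareto_front(generate_alternatives(synth_config(n = 15, seed = s))))
  }, numeric(1))
  expect_true(all(fronts >= 2))
})
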