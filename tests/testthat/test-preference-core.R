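specs <- canonical_objectives()

rec <- function(cost, pain, fn, sess, weeks) {
  c(cost_eur = cost, pain_net_change_pct = pain, function_net_change_pct = fn,
    supervised_sessions = sess, period_weeks = weeks)
}

test_that("dominance respects directions and requires a strict improvement", {
  a <- rec(100, 20, 20, 5, 10)
  expect_false(dominates(a, a, specs))                      # a == a
  expect_true(dominates(a, rec(200, 15, 18, 8, 12), specs)) # better everywhere
  # cheaper but less pain reduction: incomparable both ways
  b <- rec(50, 25, 20, 5, 10)
  cheaper <- rec(40, 10, 20, 5, 10)
  expect_false(dominates(cheaper, b, specs))
  expect_false(dominates(b, cheaper, specs))
  # weakly better plus one strict improvement dominates
  expect_true(dominates(rec(100, 20, 21, 5, 10), a, specs))
  expect_error(dominates(c(cost_eur = 1), a, specs), "missing")
})

test_that("pareto_front keeps exactly the nondominated records in input order", {
  single <- alternative_set(scenario_dataset()$records[1, ])
  expect_equal(pareto_front(single), single$records$id)

  recs <- tibble::tibble(
    id = c("dom", "x", "y"), study = "S", exercise_type = "t",
    cost_eur = c(100, 200, 300), pain_net_change_pct = c(30, 20, 10),
    function_net_change_pct = c(30, 20, 10), supervised_sessions = c(0, 5, 9),
    period_weeks = c(8, 10, 12)
  )
  expect_equal(pareto_front(alternative_set(recs)), "dom")

  withr::with_seed(42, {
    set <- random_set(200)
    expect_equal(pareto_front(set), oracle_front(set))
  })
})

test_that("ideal and nadir are the direction-aware extremes over all records", {
  single <- alternative_set(scenario_dataset()$records[2, ])
  rng <- ideal_nadir(single)
  expect_equal(rng$ideal, rng$nadir)

  set <- scenario_dataset()
  rng <- ideal_nadir(set)
  expect_equal(rng$ideal[rng$objective == "cost_eur"], 0)
  expect_equal(rng$nadir[rng$objective == "cost_eur"], 1500)
  expect_equal(rng$ideal[rng$objective == "pain_net_change_pct"], 28)
  expect_equal(rng$nadir[rng$objective == "pain_net_change_pct"], 8)
  # both extremes are attained by some record
  for (k in rng$objective) {
    expect_true(rng$ideal[rng$objective == k] %in% set$records[[k]])
    expect_true(rng$nadir[rng$objective == k] %in% set$records[[k]])
  }
})

test_that("range_status distinguishes better / within / worse on both directions", {
  cost <- preferred_range("cost_eur", 300, 600)
  expect_equal(range_status(450, cost, "minimize"), "within")
  expect_equal(range_status(250, cost, "minimize"), "better")
  expect_equal(range_status(700, cost, "minimize"), "worse")
  expect_equal(range_status(300, cost, "minimize"), "within") # bounds inclusive
  expect_equal(range_status(600, cost, "minimize"), "within")

  pain <- preferred_range("pain_net_change_pct", 15, 30)
  expect_equal(range_status(12, pain, "maximize"), "worse")
  expect_equal(range_status(20, pain, "maximize"), "within")
  expect_equal(range_status(35, pain, "maximize"), "better")
})

test_that("classification separates group I from group II and flags objectives", {
  set <- scenario_dataset()
  norm <- ideal_nadir(set)
  prefs <- example_preferences()$iteration1

  all_within <- rec(450, 20, 20, 10, 12)
  cl <- classify(all_within, prefs, specs, norm)
  expect_equal(cl$group, "I")
  expect_equal(cl$closeness, 0)
  expect_true(all(cl$status == "within"))

  over_budget <- rec(700, 20, 20, 10, 12)
  cl2 <- classify(over_budget, prefs, specs, norm)
  expect_equal(cl2$group, "II")
  expect_gt(cl2$closeness, 0)
  expect_equal(unname(cl2$status[["cost_eur"]]), "worse")

  # all better than the good-side bounds still counts as group I
  all_better <- rec(100, 40, 40, 0, 6)
  # period 6 is below the aspiration 8 on the good side
  cl3 <- classify(all_better, prefs, specs, norm)
  expect_equal(cl3$group, "I")
  expect_true(all(cl3$status %in% c("better", "within")))
  expect_equal(unname(cl3$status[["cost_eur"]]), "better")
  expect_equal(unname(cl3$status[["period_weeks"]]), "better")
  expect_equal(cl3$closeness, 0)
})

test_that("closeness is the sum of ideal-nadir-normalized reservation violations", {
  # hand oracle: cost 700 vs upper 600, observed span 100..1500 -> 100/1400
  norm <- tibble::tibble(
    objective = names(specs),
    direction = vapply(specs, `[[`, "", "direction"),
    units = "",
    ideal = c(100, 40, 40, 0, 8),
    nadir = c(1500, 0, 0, 40, 52)
  )
  class(norm) <- c("ideal_nadir", class(norm))
  prefs <- example_preferences()$iteration1
  one_violation <- rec(700, 20, 20, 10, 12)
  expect_equal(closeness_score(one_violation, prefs, specs, norm), 100 / 1400)

  two_violations <- rec(700, 10, 20, 10, 12)
  expect_equal(closeness_score(two_violations, prefs, specs, norm),
               100 / 1400 + (15 - 10) / 40)
})

test_that("select_compromises ranks group I first and fills with closest group II", {
  set <- scenario_dataset()
  prefs <- example_preferences()$iteration1

  sel <- select_compromises(set, prefs, k = 4)
  expect_equal(nrow(sel$selection), 4)
  expect_equal(sum(sel$selection$group == "I"), 1)
  expect_equal(sel$selection$group, c("I", "II", "II", "II"))
  # group II fill is in ascending closeness
  g2 <- sel$selection$closeness[sel$selection$group == "II"]
  expect_true(all(diff(g2) >= 0))

  # k at least the pool size returns the whole pool, group I first
  all_sel <- select_compromises(set, prefs, k = 100)
  expect_equal(nrow(all_sel$selection), length(all_sel$pool_ids))
  expect_equal(order(all_sel$selection$group), seq_len(nrow(all_sel$selection)))

  expect_error(select_compromises(set, prefs, k = 0), "positive")
})

test_that("dominated records are excluded from the pool unless asked for", {
  recs <- scenario_dataset()$records
  dominated <- recs[1, ]
  dominated$id <- "worse-yoga"
  dominated$cost_eur <- dominated$cost_eur + 50
  dominated$supervised_sessions <- dominated$supervised_sessions + 2
  set <- alternative_set(rbind(recs, dominated))
  prefs <- example_preferences()$iteration1

  sel <- select_compromises(set, prefs, k = 20)
  expect_false("worse-yoga" %in% sel$selection$id)
  sel_all <- select_compromises(set, prefs, k = 20, restrict_to_front = FALSE)
  expect_true("worse-yoga" %in% sel_all$selection$id)
})
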