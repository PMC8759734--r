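#' Worked-example preference sets
#'
#' The two preference sets used in the package's worked example, one per
#' iteration of the interactive loop. Iteration 1 asks for a therapy
#' costing 300-600 EUR, improving pain by 15-30% and function by 15-25%,
#' with at most 15 supervised sessions over 8-26 weeks. Iteration 2 shifts
#' the emphasis to function improvement (up to +40%), accepts more
#' supervised sessions (up to 30) and a tighter budget (200-500 EUR).
#'
#' @return A named list of two [preference_set()] objects, `iteration1` and
#'   `iteration2`.
#' @export
example_preferences <- function() {
  list(
    iteration1 = preference_set(
      preferred_range("cost_eur", 300, 600),
      preferred_range("pain_net_change_pct", 15, 30),
      preferred_range("function_net_change_pct", 15, 25),
      preferred_range("supervised_sessions", 0, 15),
      preferred_range("period_weeks", 8, 26)
    ),
    iteration2 = preference_set(
      preferred_range("cost_eur", 200, 500),
      preferred_range("pain_net_change_pct", 15, 25),
      preferred_range("function_net_change_pct", 15, 40),
      preferred_range("supervised_sessions", 0, 30),
      preferred_range("period_weeks", 12, 26)
    )
  )
}

#' Default physiotherapy fee schedule
#'
#' The packaged fee schedule (Finnish price level, early 2021): supervised
#' individual sessions at 100/75/50 EUR for 60/45/30 minutes, supervised
#' group-of-five sessions at 20/15/10 EUR (one fifth of the individual
#' fee), unsupervised facility sessions at a flat 10 EUR, home sessions
#' free, phone/text check-ins at 10 EUR, and no equipment fee. Users in
#' other settings supply their own [fee_schedule()].
#'
#' @return A [fee_schedule()].
#' @export
default_fee_schedule <- function() {
  fee_schedule(
    data.frame(
      setting = c(rep("supervised_individual", 3), rep("supervised_group5", 3),
                  "unsupervised_facility", "unsupervised_home", "contact"),
      duration_min = c(60, 45, 30, 60, 45, 30, NA, NA, NA),
      unit_fee_eur = c(100, 75, 50, 20, 15, 10, 10, 0, 10)
    ),
    equipment_fee_eur = 0
  )
}

#' Read or write a fee schedule as JSON
#'
#' @param path JSON file path.
#' @return `read_fee_schedule()` returns a [fee_schedule()];
#'   `write_fee_schedule()` returns `path` invisibly.
#' @export
read_fee_schedule <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- as.data.frame(raw$entries)
  entries$duration_min <- suppressWarnings(as.numeric(entries$duration_min))
  fee_schedule(entries, equipment_fee_eur = raw$equipment_fee_eur %||% 0)
}

#' @rdname read_fee_schedule
#' @param schedule A [fee_schedule()].
#' @export
write_fee_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "fee_schedule"))
  jsonlite::write_json(
    list(entries = schedule$entries, equipment_fee_eur = schedule$equipment_fee_eur),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Configure the synthetic alternative generator
#'
#' The generator emulates the structure of an extracted evidence table of
#' exercise-therapy interventions: five mixed min/max objectives with a
#' genuine cost/effort vs. efficacy conflict. Defaults mirror the worked
#' example's evidence base: 31 intervention arms drawn from 21 synthetic
#' studies, costs 0-1500 EUR, net pain/function improvements between -5 and
#' 45%, 0-40 supervised sessions, 8-52 week treatment periods, with
#' moderate coupling between spend and efficacy.
#'
#' @param n Number of alternatives (>= 1).
#' @param seed Integer seed; generation is deterministic given the config.
#' @param n_studies Number of distinct synthetic source studies; arms are
#'   spread over them (some studies contribute two arms).
#' @param cost_range,efficacy_range,sessions_range,period_range Objective
#'   value ranges (EUR, %, sessions, weeks); values are clipped to them.
#' @param tradeoff_strength In `[0, 1]`: how strongly efficacy follows the
#'   latent resource-intensity driver that also sets cost and sessions. At
#'   1 with no noise, cost order equals efficacy order exactly; at 0,
#'   efficacy is independent.
#' @param noise_sd Gaussian noise (in % points) added to each efficacy
#'   objective before clipping.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n = 31, seed = 1,
                         n_studies = max(1L, ceiling(n * 21 / 31)),
                         cost_range = c(0, 1500),
                         efficacy_range = c(-5, 45),
                         sessions_range = c(0, 40),
                         period_range = c(8, 52),
                         tradeoff_strength = 0.6,
                         noise_sd = 4) {
  stopifnot(n >= 1, n == round(n))
  for (r in list(cost_range, efficacy_range, sessions_range, period_range)) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2]) {
      stop("ranges must be finite c(min, max) with min < max", call. = FALSE)
    }
  }
  if (tradeoff_strength < 0 || tradeoff_strength > 1) {
    stop("tradeoff_strength must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 n_studies = as.integer(min(n_studies, n)),
                 cost_range = cost_range, efficacy_range = efficacy_range,
                 sessions_range = sessions_range, period_range = period_range,
                 tradeoff_strength = tradeoff_strength, noise_sd = noise_sd),
            class = "synth_config")
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic alternative set
#'
#' Draws `n` intervention arms under a latent resource-intensity driver:
#' cost and the number of supervised sessions increase with intensity,
#' and the two efficacy objectives follow intensity with weight
#' `tradeoff_strength` (plus an independent uniform component and Gaussian
#' noise), so cheap-but-modest and costly-but-effective alternatives
#' genuinely conflict and neither extreme dominates. Treatment period is
#' drawn independently. Sessions and periods are integers; all values are
#' clipped to the configured ranges. Ids are `synth-001 ... synth-n`.
#'
#' @param config A [synth_config()].
#' @return An [alternative_set()].
#' @examples
#' set <- generate_alternatives(synth_config(n = 10, seed = 7))
#' pareto_front(set)
#' @export
generate_alternatives <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_preserved_seed(config$seed, {
    n <- config$n
    u <- stats::runif(n)
    span <- function(r) r[2] - r[1]
    cost <- config$cost_range[1] + u * span(config$cost_range)
    sessions <- round(config$sessions_range[1] + u * span(config$sessions_range))
    efficacy <- function() {
      e <- config$tradeoff_strength * u +
        (1 - config$tradeoff_strength) * stats::runif(n)
      val <- config$efficacy_range[1] + e * span(config$efficacy_range) +
        stats::rnorm(n, 0, config$noise_sd)
      pmin(pmax(val, config$efficacy_range[1]), config$efficacy_range[2])
    }
    pain <- efficacy()
    fn <- efficacy()
    period <- round(config$period_range[1] + stats::runif(n) * span(config$period_range))
    study_idx <- sort(rep_len(seq_len(config$n_studies), n))
    records <- tibble::tibble(
      id = sprintf("synth-%03d", seq_len(n)),
      study = sprintf("Synthetic study %02d (20%02d)", study_idx,
                      10 + (study_idx %% 12)),
      exercise_type = sample(c("aerobic", "resistance", "resistance+aerobic",
                               "yoga", "tai-chi", "aquatic", "home-program"),
                             n, replace = TRUE),
      cost_eur = round(cost, 2),
      pain_net_change_pct = round(pain, 2),
      function_net_change_pct = round(fn, 2),
      supervised_sessions = pmin(pmax(sessions, config$sessions_range[1]),
                                 config$sessions_range[2]),
      period_weeks = pmin(pmax(period, config$period_range[1]),
                          config$period_range[2]),
      n_exercise = sample(15:60, n, replace = TRUE),
      n_control = sample(15:60, n, replace = TRUE)
    )
    alternative_set(records)
  })
}

#' Synthetic worked-example scenario dataset
#'
#' A hand-built, fixed set of eight synthetic intervention arms engineered
#' so that the packaged [example_preferences()] reproduce the worked
#' example's iteration pattern: with `k = 4`, iteration 1 yields exactly
#' one fully satisfying (group I) therapy, and iteration 2 yields exactly
#' three, with the final choice being the mixed resistance+aerobic arm with
#' the largest function improvement. The record values are synthetic
#' stand-ins, not extracted trial data; substituting a real evidence table
#' (via [read_alternatives()]) upgrades any analysis built on this fixture
#' from pattern-level to exact.
#'
#' All eight records are mutually nondominated, so the whole set is its own
#' Pareto front.
#'
#' @return An [alternative_set()] with 8 records.
#' @export
scenario_dataset <- function() {
  records <- tibble::tribble(
    ~id, ~study, ~exercise_type,
    ~cost_eur, ~pain_net_change_pct, ~function_net_change_pct,
    ~supervised_sessions, ~period_weeks,
    "cheung-yoga",          "Cheung-like arm (synthetic)",          "yoga",                 550,  16, 17,  8, 10,
    "krasilshchikov-mixed", "Krasilshchikov-like arm (synthetic)",  "resistance+aerobic",   480,  22, 38, 24, 12,
    "braghin-strength",     "Braghin-like arm (synthetic)",         "resistance",           320,  18, 22, 20, 16,
    "lin-taichi",           "Lin-like arm (synthetic)",             "tai-chi",              450,  16, 30, 26, 24,
    "home-program",         "Home programme arm (synthetic)",       "home-program",           0,   8,  6,  0, 12,
    "intensive-individual", "Intensive supervised arm (synthetic)", "resistance",          1500,  28, 45, 36, 26,
    "aquatic-group",        "Aquatic group arm (synthetic)",        "aquatic",              700,  12, 20, 18, 20,
    "longterm-light",       "Long light programme arm (synthetic)", "aerobic",              250,  20, 18, 10, 52
  )
  records$n_exercise <- c(18L, 20L, 25L, 32L, 24L, 15L, 27L, 30L)
  records$n_control <- c(18L, 19L, 24L, 31L, 25L, 14L, 26L, 29L)
  alternative_set(records)
}
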