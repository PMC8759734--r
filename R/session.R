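#' Start an interactive selection session
#'
#' Opens the interactive loop over an alternative set: the feasible range of
#' every objective (its best and worst observed values) is computed up front
#' for display, and the number of compromises to show per iteration, `k`, is
#' fixed for the session's lifetime (changing `k` means starting a new
#' session). Optionally the alternative set is pre-filtered by exercise type
#' before the session begins.
#'
#' The session object is environment-backed: [run_iteration()] and
#' [finish_session()] update it in place, mirroring the stateful loop a
#' decision-maker walks through.
#'
#' @param dataset A nonempty [alternative_set()].
#' @param k Number of compromise therapies shown each iteration.
#' @param include_types,exclude_types Optional exercise-type pre-filters
#'   (see [filter_exercise_types()]).
#' @return An object of class `therapy_session`.
#' @examples
#' s <- start_session(scenario_dataset(), k = 4)
#' s$ideal_nadir
#' @export
start_session <- function(dataset, k, include_types = NULL, exclude_types = NULL) {
  stopifnot(inherits(dataset, "alternative_set"))
  if (!is.null(include_types) || !is.null(exclude_types)) {
    dataset <- filter_exercise_types(dataset, include_types, exclude_types)
  }
  if (!nrow(dataset$records)) stop("alternative set is empty", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  s <- new.env(parent = emptyenv())
  s$dataset <- dataset
  s$k <- as.integer(k)
  s$history <- list()
  s$state <- "awaiting_preferences"
  s$chosen <- NULL
  s$ideal_nadir <- ideal_nadir(dataset)
  class(s) <- "therapy_session"
  s
}

#' @export
print.therapy_session <- function(x, ...) {
  cat(sprintf("<therapy_session> %d alternatives, k = %d, %d iteration(s), state: %s\n",
              nrow(x$dataset$records), x$k, length(x$history), x$state))
  if (!is.null(x$chosen)) cat("chosen:", x$chosen, "\n")
  invisible(x)
}

#' Run one iteration of the interactive loop
#'
#' Solves the selection problem for the supplied preferred ranges
#' (delegating to [select_compromises()]), appends the result to the
#' session history, and leaves the session awaiting the next preference
#' set or a final choice. Earlier iteration results are never modified.
#'
#' @param session A [start_session()] object in state
#'   `"awaiting_preferences"`.
#' @param prefs A [preference_set()] covering every objective.
#' @return An object of class `iteration_result`: the
#'   `compromise_selection` plus `index` (1-based) and `timestamp`
#'   (excluded from determinism comparisons).
#' @export
run_iteration <- function(session, prefs) {
  stopifnot(inherits(session, "therapy_session"))
  if (session$state != "awaiting_preferences") {
    stop("session is finished; start a new session to continue", call. = FALSE)
  }
  check_prefs_cover(prefs, session$dataset$specs)
  sel <- select_compromises(session$dataset, prefs, session$k)
  res <- structure(
    c(unclass(sel),
      list(index = length(session$history) + 1L, timestamp = Sys.time())),
    class = c("iteration_result", "compromise_selection")
  )
  session$history <- c(session$history, list(res))
  res
}

#' Record the decision-maker's final choice
#'
#' Ends the session by prescribing one of the therapies shown in the
#' latest iteration. The final choice must come from the displayed
#' compromises (group II members that were shown are allowed — accepting a
#' trade-off is a legitimate outcome).
#'
#' @param session A session with at least one iteration run.
#' @param chosen_id Record id appearing in the latest iteration's selection.
#' @return The session, invisibly, now in state `"finished"`.
#' @export
finish_session <- function(session, chosen_id) {
  stopifnot(inherits(session, "therapy_session"))
  if (!length(session$history)) {
    stop("no iteration has been run yet", call. = FALSE)
  }
  latest <- session$history[[length(session$history)]]
  if (!chosen_id %in% latest$selection$id) {
    stop(sprintf("'%s' was not among the alternatives shown in the latest iteration",
                 chosen_id), call. = FALSE)
  }
  session$chosen <- chosen_id
  session$state <- "finished"
  invisible(session)
}

#' Scripted decision-maker policies
#'
#' A policy drives [simulated_dm()]: an ordered list of preference sets to
#' try, a stop rule deciding after each iteration whether the decision-maker
#' is satisfied, and a choice rule picking the prescribed therapy from the
#' final selection.
#'
#' `stop_when_group1_at_least(n)` stops once at least `n` shown
#' alternatives are group I. `choose_max(key)` / `choose_min(key)` pick the
#' shown alternative with the extreme value of one objective (ties broken
#' by id).
#'
#' @param preferences List of [preference_set()] objects, applied in order.
#' @param stop_rule Function of an `iteration_result` returning `TRUE` to
#'   stop.
#' @param choose Function of an `iteration_result` returning a record id
#'   from its selection.
#' @return A list of class `dm_policy`.
#' @export
dm_policy <- function(preferences,
                      stop_rule = stop_when_group1_at_least(3),
                      choose = choose_max("function_net_change_pct")) {
  if (!length(preferences)) stop("policy needs at least one preference set", call. = FALSE)
  ok <- vapply(preferences, inherits, logical(1), "preference_set")
  if (!all(ok)) stop("`preferences` must be preference_set objects", call. = FALSE)
  structure(list(preferences = preferences, stop_rule = stop_rule, choose = choose),
            class = "dm_policy")
}

#' @rdname dm_policy
#' @param n Minimum number of group I alternatives that satisfies the
#'   decision-maker.
#' @export
stop_when_group1_at_least <- function(n) {
  force(n)
  function(result) sum(result$selection$group == "I") >= n
}

#' @rdname dm_policy
#' @param key Objective key the choice rule ranks on.
#' @export
choose_max <- function(key) {
  force(key)
  function(result) {
    sel <- result$selection
    sel <- sel[order(-sel[[key]], sel$id), , drop = FALSE]
    sel$id[1]
  }
}

#' @rdname dm_policy
#' @export
choose_min <- function(key) {
  force(key)
  function(result) {
    sel <- result$selection
    sel <- sel[order(sel[[key]], sel$id), , drop = FALSE]
    sel$id[1]
  }
}

#' Replay a scripted decision-maker through a session
#'
#' Runs the policy's preference sets through [run_iteration()] in order.
#' After each iteration the stop rule is evaluated; when it fires, the
#' choice rule picks the prescribed therapy from the iteration just shown
#' and the session is finished. If the policy is exhausted without the stop
#' rule ever firing, an error is raised (the loop is bounded by the script
#' length).
#'
#' @param session A fresh [start_session()] object.
#' @param policy A [dm_policy()].
#' @return The finished session, invisibly.
#' @examples
#' s <- start_session(scenario_dataset(), k = 4)
#' prefs <- example_preferences()
#' simulated_dm(s, dm_policy(list(prefs$iteration1, prefs$iteration2)))
#' s$chosen
#' @export
simulated_dm <- function(session, policy) {
  stopifnot(inherits(session, "therapy_session"), inherits(policy, "dm_policy"))
  for (prefs in policy$preferences) {
    res <- run_iteration(session, prefs)
    if (isTRUE(policy$stop_rule(res))) {
      finish_session(session, policy$choose(res))
      return(invisible(session))
    }
  }
  stop("stop rule never fired within the scripted preference sequence",
       call. = FALSE)
}

dataset_digest <- function(set) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_alternatives(set, tmp)
  unname(tools::md5sum(tmp))
}

#' Export or replay a session log
#'
#' `export_log()` writes the session as JSON lines: one header object
#' (dataset digest, `k`, record count) followed by one object per iteration
#' (preferred ranges, selected ids, groups, closeness scores).
#' `replay_log()` re-runs a logged session against a dataset and checks
#' that every iteration's selection (ids and groups) is reproduced exactly.
#'
#' @param session A [start_session()] session (any state).
#' @param path Log file path (JSON lines).
#' @return `export_log()`: `path`, invisibly. `replay_log()`: the replayed
#'   session, invisibly, with attribute `identical` (`TRUE` when every
#'   selection matched the log).
#' @export
export_log <- function(session, path) {
  stopifnot(inherits(session, "therapy_session"))
  header <- list(type = "header",
                 dataset_digest = dataset_digest(session$dataset),
                 n_records = nrow(session$dataset$records),
                 k = session$k,
                 chosen = session$chosen %||% NA)
  lines <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, na = "null")
  for (res in session$history) {
    obj <- list(
      type = "iteration", index = res$index,
      prefs = lapply(res$prefs, function(r) list(lower = r$lower, upper = r$upper)),
      selection = list(ids = res$selection$id, groups = res$selection$group,
                       closeness = res$selection$closeness)
    )
    lines <- c(lines, jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname export_log
#' @param dataset The [alternative_set()] to replay against (must match the
#'   logged digest).
#' @export
replay_log <- function(path, dataset) {
  lines <- readLines(path, encoding = "UTF-8")
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  header <- objs[[1]]
  if (!identical(header$type, "header")) stop("malformed log: no header", call. = FALSE)
  if (!identical(unname(header$dataset_digest), dataset_digest(dataset))) {
    warning("dataset digest differs from the logged one; replay may diverge")
  }
  session <- start_session(dataset, k = header$k)
  identical_all <- TRUE
  for (obj in objs[-1]) {
    prefs <- preference_set(lapply(names(obj$prefs), function(k) {
      preferred_range(k, obj$prefs[[k]]$lower, obj$prefs[[k]]$upper)
    }))
    res <- run_iteration(session, prefs)
    identical_all <- identical_all &&
      identical(res$selection$id, as.character(obj$selection$ids)) &&
      identical(res$selection$group, as.character(obj$selection$groups))
  }
  attr(session, "identical") <- identical_all
  invisible(session)
}
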