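#' Preferred range for one objective
#'
#' A preferred range is the decision-maker's desirable interval
#' `[lower, upper]` for an objective, in its natural units. The bound on the
#' objective's bad side (the upper bound for a minimized objective, the
#' lower bound for a maximized one) is the binding *reservation* bound:
#' violating it excludes an alternative from group I. The bound on the good
#' side is an *aspiration* used only for ranking — values beyond it still
#' satisfy the range.
#'
#' @param objective_key Objective this range applies to.
#' @param lower,upper Bounds with `lower <= upper`.
#' @return An object of class `preferred_range`.
#' @export
preferred_range <- function(objective_key, lower, upper) {
  stopifnot(is.character(objective_key), length(objective_key) == 1L)
  if (!is.finite(lower) || !is.finite(upper) || lower > upper) {
    stop("preferred range requires finite lower <= upper", call. = FALSE)
  }
  structure(list(objective_key = objective_key,
                 lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "preferred_range")
}

#' A complete set of preferred ranges
#'
#' One [preferred_range()] per objective of the problem, covering every
#' objective exactly once.
#'
#' @param ... `preferred_range` objects, or a single list of them.
#' @param specs Objective specs the set must cover; if supplied, coverage is
#'   checked.
#' @return An object of class `preference_set`: a named list of ranges keyed
#'   by objective.
#' @examples
#' preference_set(
#'   preferred_range("cost_eur", 300, 600),
#'   preferred_range("pain_net_change_pct", 15, 30),
#'   preferred_range("function_net_change_pct", 15, 25),
#'   preferred_range("supervised_sessions", 0, 15),
#'   preferred_range("period_weeks", 8, 26)
#' )
#' @export
preference_set <- function(..., specs = NULL) {
  ranges <- list(...)
  if (length(ranges) == 1L && !inherits(ranges[[1]], "preferred_range")) {
    ranges <- ranges[[1]]
  }
  ok <- vapply(ranges, inherits, logical(1), "preferred_range")
  if (!all(ok)) stop("all arguments must be preferred_range objects", call. = FALSE)
  keys <- vapply(ranges, `[[`, "", "objective_key")
  if (anyDuplicated(keys)) {
    stop("objective covered more than once: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  names(ranges) <- keys
  ps <- structure(ranges, class = "preference_set")
  if (!is.null(specs)) check_prefs_cover(ps, as_spec_list(specs))
  ps
}

check_prefs_cover <- function(prefs, specs) {
  missing_keys <- setdiff(spec_keys(specs), names(prefs))
  if (length(missing_keys)) {
    stop("preference set is missing objective(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  invisible(prefs)
}

#' @export
print.preference_set <- function(x, ...) {
  cat("<preference_set>\n")
  for (r in x) cat(sprintf("  %s: [%g, %g]\n", r$objective_key, r$lower, r$upper))
  invisible(x)
}

#' Read or write a preference set as JSON
#'
#' The JSON shape is `{"<objective_key>": {"lower": x, "upper": y}, ...}`.
#'
#' @param path JSON file path.
#' @param specs Optional objective specs to validate coverage against.
#' @return `read_preferences()` returns a [preference_set()];
#'   `write_preferences()` returns `path` invisibly.
#' @export
read_preferences <- function(path, specs = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranges <- lapply(names(raw), function(k) {
    preferred_range(k, raw[[k]]$lower, raw[[k]]$upper)
  })
  preference_set(ranges, specs = specs)
}

#' @rdname read_preferences
#' @param prefs A [preference_set()].
#' @export
write_preferences <- function(prefs, path) {
  stopifnot(inherits(prefs, "preference_set"))
  out <- lapply(prefs, function(r) list(lower = r$lower, upper = r$upper))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# reservation bound: the bad-side bound whose violation excludes group I
reservation_bound <- function(range, direction) {
  if (direction == "minimize") range$upper else range$lower
}

# aspiration bound: the good-side bound, used only for ranking
aspiration_bound <- function(range, direction) {
  if (direction == "minimize") range$lower else range$upper
}

#' Status of an objective value against a preferred range
#'
#' Classifies one objective value as `"within"` (inside the range),
#' `"better"` (beyond the range on the objective's good side — still
#' satisfying, since outcomes better than desired keep an alternative in
#' group I), or `"worse"` (beyond the reservation bound on the bad side).
#'
#' @param value Objective value.
#' @param range A [preferred_range()].
#' @param direction `"minimize"` or `"maximize"`.
#' @return One of `"better"`, `"within"`, `"worse"`.
#' @examples
#' r <- preferred_range("cost_eur", 300, 600)
#' range_status(450, r, "minimize") # "within"
#' range_status(250, r, "minimize") # "better"
#' @export
range_status <- function(value, range, direction = c("minimize", "maximize")) {
  stopifnot(inherits(range, "preferred_range"))
  direction <- match.arg(direction)
  if (value >= range$lower && value <= range$upper) return("within")
  good_side <- if (direction == "minimize") value < range$lower else value > range$upper
  if (good_side) "better" else "worse"
}

# signed violation of the reservation bound (0 when better/within)
reservation_violation <- function(value, range, direction) {
  if (direction == "minimize") max(0, value - range$upper)
  else max(0, range$lower - value)
}
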