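#' Define an objective
#'
#' An objective specification describes one axis of the multiobjective
#' problem: a short key used in data columns, a human-readable label, the
#' optimization direction, measurement units, and (optionally) the bounds of
#' a standardized outcome scale used when rescaling raw instrument scores.
#'
#' @param key Short identifier, used as a column name in alternative tables.
#' @param label Display name.
#' @param direction `"minimize"` or `"maximize"`.
#' @param units Unit string (e.g. `"EUR"`, `"%"`, `"sessions"`, `"weeks"`).
#' @param standard_scale Optional numeric `c(min, max)` with `min < max`,
#'   the standardized scale outcomes on this objective are expressed on.
#'
#' @return An object of class `objective_spec`.
#' @examples
#' objective_spec("cost_eur", "Cost", "minimize", "EUR")
#' @export
objective_spec <- function(key, label, direction = c("minimize", "maximize"),
                           units = "", standard_scale = NULL) {
  stopifnot(is.character(key), length(key) == 1L, nzchar(key))
  direction <- match.arg(direction)
  if (!is.null(standard_scale)) {
    if (!is.numeric(standard_scale) || length(standard_scale) != 2L ||
        !all(is.finite(standard_scale)) || standard_scale[1] >= standard_scale[2]) {
      stop("`standard_scale` must be numeric c(min, max) with min < max", call. = FALSE)
    }
    standard_scale <- unname(as.numeric(standard_scale))
  }
  structure(
    list(key = key, label = as.character(label), direction = direction,
         units = as.character(units), standard_scale = standard_scale),
    class = "objective_spec"
  )
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("<objective> %s (%s, %s)%s\n", x$key, x$direction, x$units,
              if (is.null(x$standard_scale)) "" else
                sprintf(" scale [%g, %g]", x$standard_scale[1], x$standard_scale[2])))
  invisible(x)
}

#' The five canonical therapy objectives
#'
#' The default objective set for comparing exercise therapy modalities:
#' minimize patient-facing cost, maximize net pain reduction and net physical
#' function improvement (both as percent improvements on standardized WOMAC
#' subscales), minimize the number of supervised training sessions, and
#' minimize the length of the treatment period.
#'
#' The WOMAC pain subscale is standardized to 0-20 and the physical function
#' subscale to 0-68; lower raw WOMAC scores indicate less pain/disability, so
#' positive net changes are improvements.
#'
#' @return A named list of five [objective_spec()] objects, in canonical axis
#'   order: `cost_eur`, `pain_net_change_pct`, `function_net_change_pct`,
#'   `supervised_sessions`, `period_weeks`.
#' @examples
#' names(canonical_objectives())
#' @export
canonical_objectives <- function() {
  specs <- list(
    objective_spec("cost_eur", "Cost", "minimize", "EUR"),
    objective_spec("pain_net_change_pct", "Pain net change", "maximize", "%",
                   standard_scale = c(0, 20)),
    objective_spec("function_net_change_pct", "Function net change", "maximize", "%",
                   standard_scale = c(0, 68)),
    objective_spec("supervised_sessions", "Supervised sessions", "minimize", "sessions"),
    objective_spec("period_weeks", "Treatment period", "minimize", "weeks")
  )
  names(specs) <- vapply(specs, `[[`, "", "key")
  specs
}

# internal: validate a list of objective_spec, return named list keyed by key
as_spec_list <- function(specs) {
  if (inherits(specs, "objective_spec")) specs <- list(specs)
  ok <- vapply(specs, inherits, logical(1), "objective_spec")
  if (!all(ok)) stop("`specs` must be a list of objective_spec objects", call. = FALSE)
  keys <- vapply(specs, `[[`, "", "key")
  if (anyDuplicated(keys)) stop("duplicate objective keys: ",
                                paste(unique(keys[duplicated(keys)]), collapse = ", "),
                                call. = FALSE)
  names(specs) <- keys
  specs
}

spec_keys <- function(specs) vapply(specs, `[[`, "", "key")

spec_directions <- function(specs) vapply(specs, `[[`, "", "direction")
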