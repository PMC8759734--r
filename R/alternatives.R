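#' Build a set of therapy alternatives
#'
#' An alternative set couples an ordered list of objectives with a table of
#' therapy records, one row per intervention arm. Each record carries a
#' unique id, provenance (source study citation, exercise type), one finite
#' value per objective, and optional arm sizes.
#'
#' @param records A data frame (or tibble) with columns `id`, `study`,
#'   `exercise_type`, one numeric column per objective key, and optionally
#'   `n_exercise` / `n_control`.
#' @param specs List of [objective_spec()]; defaults to the five canonical
#'   therapy objectives.
#'
#' @return An object of class `alternative_set` with elements `specs`
#'   (named list of objective specs) and `records` (tibble).
#' @examples
#' recs <- tibble::tibble(
#'   id = c("a", "b"), study = c("A 2020", "B 2021"), exercise_type = "aerobic",
#'   cost_eur = c(100, 400), pain_net_change_pct = c(10, 25),
#'   function_net_change_pct = c(12, 20), supervised_sessions = c(0, 12),
#'   period_weeks = c(8, 12)
#' )
#' alternative_set(recs)
#' @export
alternative_set <- function(records, specs = canonical_objectives()) {
  specs <- as_spec_list(specs)
  records <- tibble::as_tibble(records)
  validate_records(records, specs)
  structure(list(specs = specs, records = records), class = "alternative_set")
}

validate_records <- function(records, specs) {
  keys <- spec_keys(specs)
  meta <- c("id", "study", "exercise_type")
  missing_cols <- setdiff(c(meta, keys), names(records))
  if (length(missing_cols)) {
    stop("records are missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records)) {
    if (anyDuplicated(records$id)) {
      stop("duplicate record ids: ",
           paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
           call. = FALSE)
    }
    for (k in keys) {
      v <- records[[k]]
      if (!is.numeric(v) || !all(is.finite(v))) {
        bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
        stop(sprintf("objective '%s' has missing or non-finite values (rows %s)",
                     k, paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
      }
    }
    if ("supervised_sessions" %in% keys) {
      s <- records$supervised_sessions
      if (any(s < 0) || any(s != round(s))) {
        stop("supervised_sessions must be nonnegative integers", call. = FALSE)
      }
    }
    if ("period_weeks" %in% keys && any(records$period_weeks <= 0)) {
      stop("period_weeks must be positive", call. = FALSE)
    }
    if ("cost_eur" %in% keys && any(records$cost_eur < 0)) {
      stop("cost_eur must be nonnegative", call. = FALSE)
    }
  }
  invisible(records)
}

#' @export
print.alternative_set <- function(x, ...) {
  cat(sprintf("<alternative_set> %d records x %d objectives (%s)\n",
              nrow(x$records), length(x$specs),
              paste(spec_keys(x$specs), collapse = ", ")))
  print(x$records, n = 8)
  invisible(x)
}

#' @export
format.alternative_set <- function(x, ...) {
  sprintf("<alternative_set: %d records, %d objectives>",
          nrow(x$records), length(x$specs))
}

# internal: objective values as a plain numeric matrix, rows = records
objective_matrix <- function(set) {
  keys <- spec_keys(set$specs)
  m <- as.matrix(set$records[, keys, drop = FALSE])
  rownames(m) <- set$records$id
  m
}

# internal: matrix with every column oriented so smaller is better
minimization_matrix <- function(set) {
  m <- objective_matrix(set)
  dirs <- spec_directions(set$specs)
  m[, dirs == "maximize"] <- -m[, dirs == "maximize", drop = FALSE]
  m
}

#' Filter an alternative set by exercise type
#'
#' Optional pre-filtering by the free-text `exercise_type` tag, applied
#' before a session starts when the decision-maker wants only certain
#' exercise classes considered (or some excluded).
#'
#' @param set An [alternative_set()].
#' @param include Character vector of exercise types to keep (default: all).
#' @param exclude Character vector of exercise types to drop.
#' @return A filtered `alternative_set`.
#' @export
filter_exercise_types <- function(set, include = NULL, exclude = NULL) {
  stopifnot(inherits(set, "alternative_set"))
  keep <- rep(TRUE, nrow(set$records))
  if (!is.null(include)) keep <- keep & set$records$exercise_type %in% include
  if (!is.null(exclude)) keep <- keep & !(set$records$exercise_type %in% exclude)
  alternative_set(set$records[keep, , drop = FALSE], set$specs)
}
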