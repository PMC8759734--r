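#' Classify one alternative against a preference set
#'
#' An alternative is group I when every objective's value satisfies its
#' preferred range (status `"within"`, or `"better"` — beyond the range on
#' the good side); it is group II when at least one reservation bound is
#' violated. The closeness score is 0 exactly for group I members.
#'
#' @param record Named numeric vector or one-row data frame of objective
#'   values (a row of an alternative set's records).
#' @param prefs A [preference_set()] covering the specs.
#' @param specs Objective specs.
#' @param norm An [ideal_nadir()] snapshot used to normalize violations.
#' @return A list of class `classified_alternative` with elements `id`,
#'   `group` (`"I"` or `"II"`), `status` (named character vector per
#'   objective), and `closeness`.
#' @seealso [closeness_score()], [select_compromises()]
#' @export
classify <- function(record, prefs, specs, norm) {
  specs <- as_spec_list(specs)
  check_prefs_cover(prefs, specs)
  keys <- spec_keys(specs)
  id <- if (is.data.frame(record) && "id" %in% names(record)) record$id[1] else
    attr(record, "id") %||% NA_character_
  v <- objective_vector(record, keys)
  names(v) <- keys
  status <- vapply(keys, function(k) {
    range_status(v[[k]], prefs[[k]], specs[[k]]$direction)
  }, character(1))
  group <- if (any(status == "worse")) "II" else "I"
  structure(
    list(id = id, group = group, status = status,
         closeness = closeness_score(record, prefs, specs, norm)),
    class = "classified_alternative"
  )
}

#' Closeness of an alternative to the preferred ranges
#'
#' Aggregates how far an alternative falls outside the preferred ranges:
#' the sum over objectives of the reservation-bound violation (distance
#' from the value to the nearest group-I-eligible value on that objective;
#' 0 for satisfied objectives), each normalized by the objective's observed
#' ideal-nadir width. Degenerate objectives (all records equal) use a
#' normalizer of 1 and can never contribute a violation differential. The
#' score is 0 if and only if the alternative is group I.
#'
#' The L1 aggregation is deliberately pluggable (see
#' [select_compromises()]'s internals); a Chebyshev/max rule could be
#' substituted without touching classification semantics.
#'
#' @inheritParams classify
#' @return Nonnegative closeness score.
#' @export
closeness_score <- function(record, prefs, specs, norm) {
  specs <- as_spec_list(specs)
  check_prefs_cover(prefs, specs)
  keys <- spec_keys(specs)
  v <- objective_vector(record, keys)
  names(v) <- keys
  width <- in_normalizers(norm)
  sum(vapply(keys, function(k) {
    reservation_violation(v[[k]], prefs[[k]], specs[[k]]$direction) / width[[k]]
  }, numeric(1)))
}

# ranking distance for group I members: ideal-nadir-normalized L1 distance
# to the aspiration corner (the vector of good-side bounds)
aspiration_distance <- function(record, prefs, specs, norm) {
  keys <- spec_keys(specs)
  v <- objective_vector(record, keys)
  names(v) <- keys
  width <- in_normalizers(norm)
  sum(vapply(keys, function(k) {
    asp <- aspiration_bound(prefs[[k]], specs[[k]]$direction)
    abs(v[[k]] - asp) / width[[k]]
  }, numeric(1)))
}

# classify every record of a set; returns one tibble row per record
classify_set <- function(set, prefs, norm = ideal_nadir(set)) {
  specs <- set$specs
  keys <- spec_keys(specs)
  rows <- lapply(seq_len(nrow(set$records)), function(i) {
    rec <- set$records[i, , drop = FALSE]
    cl <- classify(rec, prefs, specs, norm)
    tibble::tibble(
      id = rec$id, group = cl$group,
      status = list(cl$status),
      closeness = cl$closeness,
      aspiration_dist = aspiration_distance(rec, prefs, specs, norm)
    )
  })
  do.call(rbind, rows)
}

#' Select the top-k compromise therapies for a preference set
#'
#' The selection step of one iteration: the candidate pool is the Pareto
#' front (by default — every shown therapy is then a genuine compromise),
#' each candidate is classified against the preferred ranges, and `k`
#' alternatives are chosen. All group I candidates come first, ranked by
#' ascending normalized L1 distance to the aspiration corner; if fewer than
#' `k` exist, the remaining slots are filled with group II candidates in
#' ascending closeness. Ties break lexicographically by `(score, id)`, so
#' the output order is deterministic and invariant under row permutation of
#' the input.
#'
#' @param set An [alternative_set()].
#' @param prefs A [preference_set()] covering the set's objectives.
#' @param k Number of alternatives to show (positive integer).
#' @param restrict_to_front If `TRUE` (default), only nondominated records
#'   are candidates; set `FALSE` to allow dominated records for exploratory
#'   use.
#' @return A list of class `compromise_selection`: `selection` (tibble of
#'   the chosen alternatives with `id`, `group`, per-objective `status`
#'   list-column, `closeness`, `aspiration_dist`, joined with the record
#'   columns), `classified` (the full classified pool), `ideal_nadir`,
#'   `prefs`, `k`, and `pool_ids`.
#' @examples
#' set <- scenario_dataset()
#' sel <- select_compromises(set, example_preferences()$iteration1, k = 4)
#' sel$selection[, c("id", "group", "closeness")]
#' @export
select_compromises <- function(set, prefs, k, restrict_to_front = TRUE) {
  stopifnot(inherits(set, "alternative_set"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (!nrow(set$records)) stop("alternative set is empty", call. = FALSE)
  check_prefs_cover(prefs, set$specs)
  norm <- ideal_nadir(set)
  pool_ids <- if (restrict_to_front) pareto_front(set) else set$records$id
  pool <- alternative_set(
    set$records[match(pool_ids, set$records$id), , drop = FALSE], set$specs
  )
  cl <- classify_set(pool, prefs, norm)
  g1 <- cl[cl$group == "I", , drop = FALSE]
  g2 <- cl[cl$group == "II", , drop = FALSE]
  g1 <- g1[order(g1$aspiration_dist, g1$id), , drop = FALSE]
  g2 <- g2[order(g2$closeness, g2$id), , drop = FALSE]
  chosen <- utils::head(rbind(g1, g2), k)
  selection <- cbind(
    chosen,
    pool$records[match(chosen$id, pool$records$id),
                 setdiff(names(pool$records), "id"), drop = FALSE]
  )
  structure(
    list(selection = tibble::as_tibble(selection),
         classified = tibble::as_tibble(cl),
         ideal_nadir = norm, prefs = prefs, k = as.integer(k),
         pool_ids = pool_ids),
    class = "compromise_selection"
  )
}

#' @export
print.compromise_selection <- function(x, ...) {
  n1 <- sum(x$selection$group == "I")
  cat(sprintf("<compromise_selection> %d shown (k = %d): %d group I, %d group II\n",
              nrow(x$selection), x$k, n1, nrow(x$selection) - n1))
  print(x$selection[, c("id", "group", "closeness", "aspiration_dist")])
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
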