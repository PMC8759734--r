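#' Pareto dominance between two records
#'
#' Record `a` dominates record `b` when `a` is at least as good as `b` on
#' every objective (respecting each objective's direction) and strictly
#' better on at least one.
#'
#' @param a,b Named numeric vectors (or one-row data frames) of objective
#'   values sharing the spec keys.
#' @param specs Objective specs giving each objective's direction.
#' @return `TRUE` or `FALSE`.
#' @export
dominates <- function(a, b, specs = canonical_objectives()) {
  specs <- as_spec_list(specs)
  keys <- spec_keys(specs)
  a <- objective_vector(a, keys)
  b <- objective_vector(b, keys)
  sgn <- ifelse(spec_directions(specs) == "minimize", 1, -1)
  da <- sgn * a
  db <- sgn * b
  all(da <= db) && any(da < db)
}

objective_vector <- function(x, keys) {
  if (is.data.frame(x)) x <- unlist(x[1, intersect(keys, names(x)), drop = FALSE])
  if (is.null(names(x)) && length(x) == length(keys)) names(x) <- keys
  missing_keys <- setdiff(keys, names(x))
  if (length(missing_keys)) {
    stop("objective value(s) missing: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  as.numeric(x[keys])
}

#' Nondominated records of an alternative set
#'
#' Returns the ids of records not Pareto-dominated by any other record —
#' the compromise therapies among which no objective can be improved
#' without impairing another. Input order is preserved; duplicated
#' objective vectors are mutually nondominating, so ties all survive.
#'
#' @param set An [alternative_set()].
#' @return Character vector of record ids, in input order.
#' @export
pareto_front <- function(set) {
  stopifnot(inherits(set, "alternative_set"))
  if (!nrow(set$records)) stop("alternative set is empty", call. = FALSE)
  m <- minimization_matrix(set)
  n <- nrow(m)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    # rows weakly better than i everywhere, strictly somewhere
    le <- m <= matrix(m[i, ], n, ncol(m), byrow = TRUE)
    lt <- m < matrix(m[i, ], n, ncol(m), byrow = TRUE)
    dominated[i] <- any(rowSums(le) == ncol(m) & rowSums(lt) > 0)
  }
  set$records$id[!dominated]
}

#' Best and worst observed values per objective
#'
#' Computes the ideal (best observed) and nadir (worst observed) value of
#' each objective over the whole alternative set. These are shown to the
#' decision-maker at session start so preferred ranges can be set against
#' the feasible range, and they normalize closeness scores.
#'
#' @param set An [alternative_set()].
#' @return A tibble of class `ideal_nadir` with columns `objective`,
#'   `direction`, `units`, `ideal`, `nadir`.
#' @export
ideal_nadir <- function(set) {
  stopifnot(inherits(set, "alternative_set"))
  if (!nrow(set$records)) stop("alternative set is empty", call. = FALSE)
  m <- objective_matrix(set)
  dirs <- spec_directions(set$specs)
  ideal <- ifelse(dirs == "minimize", apply(m, 2, min), apply(m, 2, max))
  nadir <- ifelse(dirs == "minimize", apply(m, 2, max), apply(m, 2, min))
  out <- tibble::tibble(
    objective = colnames(m),
    direction = unname(dirs),
    units = vapply(set$specs, `[[`, "", "units"),
    ideal = unname(ideal),
    nadir = unname(nadir)
  )
  class(out) <- c("ideal_nadir", class(out))
  out
}

# internal: |nadir - ideal| normalizer with fallback 1 for degenerate axes
in_normalizers <- function(norm) {
  width <- abs(norm$nadir - norm$ideal)
  width[width == 0] <- 1
  stats::setNames(width, norm$objective)
}
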