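canonical_columns <- function(specs = canonical_objectives()) {
  c("id", "study", "exercise_type", spec_keys(specs), "n_exercise", "n_control")
}

#' Read therapy alternatives from a delimited text file
#'
#' Loads a CSV of intervention arms (one row each) into a validated
#' [alternative_set()]. The canonical header is `id, study, exercise_type,
#' cost_eur, pain_net_change_pct, function_net_change_pct,
#' supervised_sessions, period_weeks, n_exercise, n_control`; files with
#' different column names are remapped through a dialect.
#'
#' When the `id` column is absent, ids are generated deterministically by
#' slugifying `study` plus the exercise-type tag (with a numeric suffix for
#' repeated combinations), so repeated parses of the same file agree.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect Optional mapping from canonical column names to the names
#'   actually used in the file: a named character vector / named list
#'   (`c(cost_eur = "price")`) or a path to a JSON file of the same shape.
#' @param specs Objective specs the file must provide values for.
#'
#' @return An [alternative_set()]; row order follows the file.
#' @seealso [write_alternatives()]
#' @export
read_alternatives <- function(path, dialect = NULL, specs = canonical_objectives()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  specs <- as_spec_list(specs)
  dialect <- load_dialect(dialect)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  # rename actual -> canonical
  for (canon in names(dialect)) {
    actual <- dialect[[canon]]
    if (!actual %in% names(df)) {
      stop(sprintf("dialect maps '%s' to column '%s', absent from %s",
                   canon, actual, path), call. = FALSE)
    }
    names(df)[names(df) == actual] <- canon
  }
  keys <- spec_keys(specs)
  missing_cols <- setdiff(c("study", keys), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"exercise_type" %in% names(df)) df$exercise_type <- NA_character_
  for (k in keys) {
    v <- suppressWarnings(as.numeric(df[[k]]))
    bad <- which(is.na(v) & !is.na(df[[k]]) & nzchar(trimws(as.character(df[[k]]))))
    if (length(bad)) {
      stop(sprintf("non-numeric value in objective column '%s' at data row %d",
                   k, bad[1]), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in objective column '%s' at data row %d",
                   k, which(is.na(v))[1]), call. = FALSE)
    }
    df[[k]] <- v
  }
  if (!"id" %in% names(df)) df$id <- generate_ids(df$study, df$exercise_type)
  df$id <- as.character(df$id)
  for (nm in c("n_exercise", "n_control")) {
    if (nm %in% names(df)) df[[nm]] <- suppressWarnings(as.integer(df[[nm]]))
  }
  keep <- intersect(canonical_columns(specs), names(df))
  alternative_set(df[, keep, drop = FALSE], specs)
}

#' Write therapy alternatives to a delimited text file
#'
#' Writes the canonical CSV representation; [read_alternatives()] on the
#' result reproduces the set field for field (UTF-8, so non-ASCII study
#' names survive the round trip).
#'
#' @param set An [alternative_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_alternatives <- function(set, path) {
  stopifnot(inherits(set, "alternative_set"))
  cols <- intersect(canonical_columns(set$specs), names(set$records))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(set$records[, cols, drop = FALSE], con, row.names = FALSE,
                   quote = TRUE, na = "")
  invisible(path)
}

load_dialect <- function(dialect) {
  if (is.null(dialect)) return(list())
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect) &&
      grepl("\\.json$", dialect, ignore.case = TRUE)) {
    dialect <- jsonlite::read_json(dialect, simplifyVector = TRUE)
  }
  dialect <- as.list(dialect)
  if (length(dialect) && (is.null(names(dialect)) || any(!nzchar(names(dialect))))) {
    stop("dialect must be a named mapping canonical -> actual column name",
         call. = FALSE)
  }
  dialect
}

slugify <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9]+", "-", x)
  gsub("(^-)|(-$)", "", x)
}

generate_ids <- function(study, arm_label) {
  arm_label[is.na(arm_label)] <- ""
  base <- paste(slugify(study), slugify(arm_label), sep = "-")
  base <- gsub("(^-)|(-$)", "", base)
  ave(base, base, FUN = function(b) {
    if (length(b) == 1L) b else paste0(b, "-", seq_along(b))
  })
}
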