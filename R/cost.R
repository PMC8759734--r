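fee_settings <- c("supervised_individual", "supervised_group5",
                  "unsupervised_facility", "unsupervised_home", "contact")

#' Build a fee schedule
#'
#' A fee schedule lists the per-session unit fees used to estimate the
#' patient-facing cost of a therapy: supervised sessions with an individual
#' instructor or in a group of five (fees depend on session duration),
#' unsupervised sessions at a facility or at home (flat per-session fees,
#' duration-independent), check-in contacts (phone call / text message), and
#' a one-off equipment fee.
#'
#' @param entries Data frame with columns `setting` (one of
#'   `supervised_individual`, `supervised_group5`, `unsupervised_facility`,
#'   `unsupervised_home`, `contact`),
#'   `duration_min` (minutes; `NA` for duration-independent settings) and
#'   `unit_fee_eur` (nonnegative).
#' @param equipment_fee_eur One-off equipment fee (default 0).
#' @return An object of class `fee_schedule`.
#' @seealso [default_fee_schedule()] for the packaged default fees.
#' @export
fee_schedule <- function(entries, equipment_fee_eur = 0) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("setting", "duration_min", "unit_fee_eur") %in% names(entries)))
  bad <- setdiff(entries$setting, fee_settings)
  if (length(bad)) stop("unknown fee setting(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(entries$unit_fee_eur < 0) || equipment_fee_eur < 0) {
    stop("fees must be nonnegative", call. = FALSE)
  }
  if (any(entries$setting == "unsupervised_home" & entries$unit_fee_eur != 0)) {
    stop("home sessions carry fee 0 by construction", call. = FALSE)
  }
  structure(list(entries = tibble::as_tibble(entries),
                 equipment_fee_eur = as.numeric(equipment_fee_eur)),
            class = "fee_schedule")
}

#' @export
print.fee_schedule <- function(x, ...) {
  cat("<fee_schedule>\n")
  print(x$entries)
  cat(sprintf("equipment fee: %g EUR\n", x$equipment_fee_eur))
  invisible(x)
}

#' Look up a unit fee
#'
#' Returns the fee for one session (or contact) of the given setting and
#' duration. Durations are matched exactly against the listed entries;
#' duration-independent settings (home, facility, contact) ignore
#' `duration_min`. Unlisted combinations are an error rather than being
#' interpolated, because the schedule lists discrete fees only.
#'
#' @param schedule A [fee_schedule()].
#' @param setting One of the schedule's settings.
#' @param duration_min Session length in minutes (ignored where fees are
#'   per-session).
#' @return The unit fee in EUR.
#' @export
unit_fee <- function(schedule, setting, duration_min = NA) {
  stopifnot(inherits(schedule, "fee_schedule"))
  e <- schedule$entries
  rows <- e$setting == setting &
    (is.na(e$duration_min) | (!is.na(duration_min) & e$duration_min == duration_min))
  if (!any(rows)) {
    stop(sprintf("no fee entry for setting '%s'%s", setting,
                 if (is.na(duration_min)) "" else sprintf(" at %g min", duration_min)),
         call. = FALSE)
  }
  e$unit_fee_eur[which(rows)[1]]
}

#' Describe an intervention's session composition
#'
#' An intervention plan records how many sessions of each kind a therapy
#' prescribes over the measurement window (baseline to outcome end-point;
#' later follow-ups are excluded), plus check-in contacts. The window is
#' stored for documentation only and does not enter the cost.
#'
#' @param items Data frame with columns `setting`, `duration_min`, `count`
#'   (nonnegative integers).
#' @param contacts Number of phone/text check-ins (nonnegative integer).
#' @param window Free-text description of the measurement window.
#' @return An object of class `intervention_plan`.
#' @examples
#' intervention_plan(
#'   data.frame(setting = "supervised_group5", duration_min = 60, count = 12),
#'   contacts = 2
#' )
#' @export
intervention_plan <- function(items = NULL, contacts = 0, window = "") {
  if (is.null(items)) {
    items <- data.frame(setting = character(), duration_min = numeric(),
                        count = integer())
  }
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  stopifnot(all(c("setting", "duration_min", "count") %in% names(items)))
  if (nrow(items) && (any(items$count < 0) || any(items$count != round(items$count)))) {
    stop("item counts must be nonnegative integers", call. = FALSE)
  }
  if (contacts < 0 || contacts != round(contacts)) {
    stop("contacts must be a nonnegative integer", call. = FALSE)
  }
  structure(list(items = tibble::as_tibble(items),
                 contacts = as.integer(contacts), window = as.character(window)),
            class = "intervention_plan")
}

#' Estimate the cost of an intervention
#'
#' Total patient-facing cost of a plan under a fee schedule: the sum over
#' plan items of `count * unit_fee`, plus `contacts` times the contact fee,
#' plus the schedule's equipment fee. Under the default schedule a purely
#' home-based plan with no contacts costs exactly 0.
#'
#' @param plan An [intervention_plan()].
#' @param schedule A [fee_schedule()]; defaults to the packaged schedule.
#' @param itemize If `TRUE`, return a breakdown tibble (one row per line
#'   item plus contacts/equipment) instead of the bare total.
#' @return Total cost in EUR, or an itemized tibble with a `total`
#'   attribute when `itemize = TRUE`.
#' @examples
#' plan <- intervention_plan(
#'   data.frame(setting = c("supervised_group5", "unsupervised_home"),
#'              duration_min = c(60, NA), count = c(12, 24)),
#'   contacts = 2
#' )
#' estimate_cost(plan) # 260
#' @export
estimate_cost <- function(plan, schedule = default_fee_schedule(), itemize = FALSE) {
  stopifnot(inherits(plan, "intervention_plan"), inherits(schedule, "fee_schedule"))
  items <- plan$items
  fees <- if (nrow(items)) {
    mapply(function(s, d) unit_fee(schedule, s, d), items$setting, items$duration_min)
  } else numeric()
  contact_fee <- if (plan$contacts > 0) unit_fee(schedule, "contact") else 0
  breakdown <- tibble::tibble(
    item = c(if (nrow(items)) paste0(items$setting,
                                     ifelse(is.na(items$duration_min), "",
                                            paste0(" ", items$duration_min, "min"))),
             "contacts", "equipment"),
    count = c(items$count, plan$contacts, 1L),
    unit_fee_eur = c(fees, contact_fee, schedule$equipment_fee_eur),
    subtotal_eur = c(items$count * fees, plan$contacts * contact_fee,
                     schedule$equipment_fee_eur)
  )
  total <- sum(breakdown$subtotal_eur)
  if (itemize) return(structure(breakdown, total = total))
  total
}
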