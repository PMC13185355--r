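#' Age in completed years at a date
#'
#' Standard epidemiologic convention: floor of elapsed whole years between
#' birth date and the reference date.
#'
#' @param birth_date,at Date vectors (recycled).
#' @return integer vector of completed years.
#' @export
age_at <- function(birth_date, at) {
  b <- as.POSIXlt(birth_date)
  a <- as.POSIXlt(at)
  yrs <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(yrs - before_birthday)
}

#' End of a patient's observation window
#'
#' The earliest of death date, HMO exit (end of the last insurance period)
#' and the data-extraction date. Elapsed-time rules (continuity of purchases,
#' length of follow-up) are measured to this date.
#'
#' @param death_date Date or NA.
#' @param insurance tibble with columns `start`, `end` (this patient's
#'   insurance periods), or a Date vector of period ends.
#' @param extraction_date Date.
#' @return Date scalar.
#' @export
observation_end <- function(death_date, insurance, extraction_date) {
  ends <- if (is.data.frame(insurance)) insurance$end else insurance
  if (length(ends) == 0 || all(is.na(ends))) {
    abort("patient has no insurance period")
  }
  ends <- max(ends, na.rm = TRUE)
  out <- min(c(ends, extraction_date), na.rm = TRUE)
  if (!is.na(death_date)) out <- min(out, death_date)
  as.Date(out, origin = "1970-01-01")
}

#' Purchase occasions and treatment span
#'
#' An occasion is a distinct purchase calendar date (same-day multi-drug
#' purchases are one clinical event); the span is last distinct date minus
#' first, in days (0 for a single occasion). Both are invariant to row order
#' and duplicated rows.
#'
#' @param purchases tibble with `purchase_date` (and `apm_class` when
#'   filtering) for one patient.
#' @param classes optional character vector of `apm_class` values to keep.
#' @return named list `occasions`, `duration_days`, `first_date`, `last_date`
#'   (dates NA when no qualifying purchase).
#' @export
#' @examples
#' p <- tibble::tibble(purchase_date = as.Date(c("2010-01-01", "2012-06-30")),
#'                     apm_class = "levodopa")
#' treatment_span(p)  # 2 occasions, 911 days
treatment_span <- function(purchases, classes = NULL) {
  dd <- purchases
  if (!is.null(classes)) dd <- dd[dd$apm_class %in% classes, , drop = FALSE]
  dates <- sort(unique(dd$purchase_date))
  if (length(dates) == 0) {
    return(list(occasions = 0L, duration_days = 0L,
                first_date = as.Date(NA), last_date = as.Date(NA)))
  }
  list(occasions = length(dates),
       duration_days = as.integer(dates[length(dates)] - dates[1]),
       first_date = dates[1], last_date = dates[length(dates)])
}
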