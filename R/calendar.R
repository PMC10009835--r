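# Monday of a given ISO week. ISO week 1 always contains January 4th.
iso_week_monday <- function(iso_year, iso_week) {
  jan4 <- as.Date(sprintf("%d-01-04", iso_year))
  wk1_monday <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  wk1_monday + 7L * (iso_week - 1L)
}

#' Build the study prompt-week calendar
#'
#' Enumerates the ISO weeks in which a weekly participation prompt is sent:
#' every ISO week whose Monday falls inside the study span, minus holiday
#' weeks when prompting is suspended. The default holiday specification
#' mimics a Danish school year: two weeks around Christmas/New Year (ISO
#' weeks 52, 53 and 1, at most two of which have Mondays in any one calendar
#' year) and a six-week summer break (ISO weeks 27--32), leaving 44 prompt
#' weeks per calendar year.
#'
#' @param start,end first and last month of the study, as `Date`s or
#'   `"YYYY-MM-DD"` strings (day-of-month is ignored; whole months are used).
#' @param holiday_weeks integer ISO week numbers excluded in every year;
#'   `integer(0)` keeps every week.
#' @return tibble with one row per prompt week: `iso_year`, `iso_week`,
#'   `monday` (the week's Monday) and `month` (first day of the calendar
#'   month containing that Monday — the month a week aggregates into).
#' @export
build_study_calendar <- function(start, end,
                                 holiday_weeks = c(52L, 53L, 1L, 27:32)) {
  start <- lubridate::floor_date(as.Date(start), "month")
  end_month <- lubridate::floor_date(as.Date(end), "month")
  if (start > end_month) stop("`start` must not be after `end`")
  end <- lubridate::ceiling_date(end_month, "month") - 1L
  days <- seq(start, end, by = "day")
  mondays <- days[format(days, "%u") == "1"]
  iso_year <- lubridate::isoyear(mondays)
  iso_week <- lubridate::isoweek(mondays)
  keep <- !(iso_week %in% holiday_weeks)
  tibble::tibble(
    iso_year = iso_year[keep],
    iso_week = iso_week[keep],
    monday = mondays[keep],
    month = lubridate::floor_date(mondays[keep], "month")
  )
}
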