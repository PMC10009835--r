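# Completed months of age on the first day of a month.
age_in_months <- function(dob, month_start) {
  12L * (lubridate::year(month_start) - lubridate::year(dob)) +
    (lubridate::month(month_start) - lubridate::month(dob)) -
    as.integer(lubridate::day(dob) > 1L)
}

#' Aggregate weekly session reports to a monthly panel
#'
#' Reduces weekly SMS responses to the child-month panel consumed by the
#' trajectory model: for each child-month, the average weekly participation
#' `y` is the sum of reported sessions divided by the number of weeks with a
#' response, and is set to missing when two or fewer weeks were answered
#' that month. A week belongs to the calendar month containing its Monday.
#' Every calendar month inside the child's enrolment window appears in the
#' panel (with `y = NA` where too few weeks were answered), and the child's
#' age in completed months is attached.
#'
#' @param weekly tibble of responses: `child_id`, `iso_year`, `iso_week`,
#'   `sessions` (0--8; out-of-range records are dropped with a warning).
#' @param calendar prompt-week calendar from [build_study_calendar()].
#' @param roster child roster with `child_id`, `dob`, and optionally
#'   `entry_month`/`exit_month` (otherwise the child's observed span is
#'   used).
#' @param min_weeks minimum answered weeks for a non-missing month
#'   (default 3, i.e. "two weekly measurements or less" is missing).
#' @return tibble: `child_id`, `month`, `age_months`, `age` (years =
#'   `age_months/12`), `y`, `n_weeks_observed`.
#' @export
aggregate_weekly_to_monthly <- function(weekly, calendar, roster,
                                        min_weeks = 3) {
  if (!all(weekly$child_id %in% roster$child_id))
    stop("weekly responses reference children missing from the roster")
  bad <- is.na(weekly$sessions) | weekly$sessions < 0 | weekly$sessions > 8
  if (any(bad)) {
    warning(sprintf("dropping %d response(s) with sessions outside 0-8",
                    sum(bad)))
    weekly <- weekly[!bad, , drop = FALSE]
  }
  wk <- dplyr::inner_join(weekly, calendar[c("iso_year", "iso_week", "month")],
                          by = c("iso_year", "iso_week"))
  if (nrow(wk) < nrow(weekly))
    warning(sprintf("dropping %d response(s) outside the prompt calendar",
                    nrow(weekly) - nrow(wk)))

  observed <- wk |>
    dplyr::group_by(.data$child_id, .data$month) |>
    dplyr::summarise(total = sum(.data$sessions),
                     n_weeks_observed = dplyr::n(), .groups = "drop")

  cal_months <- sort(unique(calendar$month))
  span <- if (all(c("entry_month", "exit_month") %in% names(roster))) {
    roster |>
      dplyr::select("child_id", "entry_month", "exit_month")
  } else {
    observed |>
      dplyr::group_by(.data$child_id) |>
      dplyr::summarise(entry_month = min(.data$month),
                       exit_month = max(.data$month), .groups = "drop")
  }
  span <- span[span$child_id %in% unique(wk$child_id), , drop = FALSE]
  grid <- span |>
    dplyr::rowwise() |>
    dplyr::mutate(month = list(
      cal_months[cal_months >= .data$entry_month &
                   cal_months <= .data$exit_month])) |>
    dplyr::ungroup() |>
    dplyr::select("child_id", "month") |>
    tidyr::unnest("month")

  panel <- grid |>
    dplyr::left_join(observed, by = c("child_id", "month")) |>
    dplyr::left_join(roster[c("child_id", "dob")], by = "child_id") |>
    dplyr::mutate(
      n_weeks_observed = dplyr::coalesce(.data$n_weeks_observed, 0L),
      y = dplyr::if_else(.data$n_weeks_observed >= min_weeks,
                         .data$total / .data$n_weeks_observed, NA_real_),
      age_months = age_in_months(.data$dob, .data$month),
      age = .data$age_months / 12
    ) |>
    dplyr::select("child_id", "month", "age_months", "age", "y",
                  "n_weeks_observed") |>
    dplyr::arrange(.data$child_id, .data$month)
  panel
}

#' Exclude children with too few monthly measurements
#'
#' Children contributing fewer than `min_months` non-missing monthly values
#' (default 2, i.e. "only one calculated monthly measurement") are removed
#' from the panel.
#'
#' @param panel monthly panel from [aggregate_weekly_to_monthly()].
#' @param min_months minimum non-missing months to be retained.
#' @return list with `panel` (filtered) and `excluded` (character ids).
#' @export
exclude_sparse_children <- function(panel, min_months = 2) {
  counts <- tapply(!is.na(panel$y), panel$child_id, sum)
  excluded <- names(counts)[counts < min_months]
  list(panel = panel[!(panel$child_id %in% excluded), , drop = FALSE],
       excluded = excluded)
}

#' Allocate reported sessions equally across reported sport types
#'
#' Each reported sport receives `sessions / n_sports`; the total is
#' conserved. Responses with sessions but no sport code are allocated to
#' "other" (code 10) with a warning.
#'
#' @param weekly tibble with `sessions` and `sport_codes` (codes 1--10
#'   separated by `;`, empty string for none), plus any id columns.
#' @return `weekly` minus `sport_codes`, expanded to one row per reported
#'   sport, with columns `sport_code`, `sport`, `allocated`.
#' @export
allocate_sport_sessions <- function(weekly) {
  codes <- strsplit(ifelse(is.na(weekly$sport_codes), "",
                           weekly$sport_codes), ";", fixed = TRUE)
  codes <- lapply(codes, function(x) as.integer(x[nzchar(x)]))
  n_codes <- lengths(codes)
  orphan <- weekly$sessions >= 1L & n_codes == 0L
  if (any(orphan)) {
    warning(sprintf("%d response(s) with sessions but no sport type; %s",
                    sum(orphan), "allocated to 'other'"))
    codes[orphan] <- list(10L)
    n_codes[orphan] <- 1L
  }
  keep <- n_codes > 0L & weekly$sessions >= 1L
  idx <- rep(which(keep), n_codes[keep])
  out <- weekly[idx, setdiff(names(weekly), "sport_codes"), drop = FALSE]
  out$sport_code <- unlist(codes[keep])
  out$sport <- sport_names[out$sport_code]
  out$allocated <- out$sessions / n_codes[keep][rep(seq_len(sum(keep)),
                                                    n_codes[keep])]
  tibble::as_tibble(out)
}

#' Sport-type profile by trajectory group
#'
#' Mean cumulative allocated sessions per group member for each sport, and
#' the percentage each sport contributes within its group (percentages per
#' group sum to 100).
#'
#' @param weekly weekly responses (see [allocate_sport_sessions()]).
#' @param assignments tibble `child_id`, `group` (modal trajectory group).
#' @return tibble: `group`, `sport`, `mean_sessions`, `pct`.
#' @export
sport_type_summary <- function(weekly, assignments) {
  if (!all(weekly$child_id %in% assignments$child_id))
    stop("responses from children with no trajectory group label")
  alloc <- allocate_sport_sessions(weekly)
  members <- assignments |>
    dplyr::count(.data$group, name = "n_members")
  alloc |>
    dplyr::inner_join(assignments, by = "child_id") |>
    dplyr::group_by(.data$group, .data$sport) |>
    dplyr::summarise(total = sum(.data$allocated), .groups = "drop") |>
    dplyr::inner_join(members, by = "group") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(mean_sessions = .data$total / .data$n_members,
                  pct = 100 * .data$total / sum(.data$total)) |>
    dplyr::ungroup() |>
    dplyr::select("group", "sport", "mean_sessions", "pct")
}
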