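# The six motor tests and whether a larger raw value means better
# performance (the shuttle run is a time: smaller is better).
motor_tests <- c("balance", "throw", "grip", "jump", "shuttle", "andersen")
motor_directions <- c(balance = 1, throw = 1, grip = 1, jump = 1,
                      shuttle = -1, andersen = 1)
health_tests <- c("grip", "andersen")
coordination_tests <- c("jump", "shuttle", "balance", "throw")

#' Orient motor-test scores so larger is always better
#'
#' Multiplies tests where a lower raw value means better performance (the
#' shuttle-run time) by -1; all other tests are unchanged. Applying the
#' orientation twice returns the original values.
#'
#' @param motor tibble with some or all of the test columns `balance`,
#'   `throw`, `grip`, `jump`, `shuttle`, `andersen`.
#' @param tests which columns to orient (default: all test columns
#'   present). Unknown test names are an error.
#' @return `motor` with oriented test columns.
#' @export
orient_scores <- function(motor, tests = intersect(motor_tests,
                                                   names(motor))) {
  unknown <- setdiff(tests, motor_tests)
  if (length(unknown))
    stop("unknown motor test(s): ", paste(unknown, collapse = ", "))
  for (t in tests) motor[[t]] <- motor[[t]] * motor_directions[[t]]
  motor
}

#' Sex- and age-stratified z-scores
#'
#' Standardises each (oriented) test within sex-by-age-category strata:
#' `z = (x - stratum mean) / stratum SD` with the sample SD (denominator
#' `n - 1`). Singleton or zero-variance strata yield missing z-scores with
#' a warning.
#'
#' @param motor tibble of oriented test values with columns `sex` and
#'   `age_bin` (see [motor_age_bin()]) plus test columns.
#' @param tests test columns to standardise.
#' @return `motor` with added columns `<test>_z`.
#' @export
stratified_zscores <- function(motor, tests = intersect(motor_tests,
                                                        names(motor))) {
  stopifnot(all(c("sex", "age_bin") %in% names(motor)))
  stratum <- interaction(motor$sex, motor$age_bin, drop = TRUE)
  degenerate <- FALSE
  for (t in tests) {
    x <- motor[[t]]
    m <- stats::ave(x, stratum, FUN = function(v) mean(v, na.rm = TRUE))
    s <- stats::ave(x, stratum, FUN = function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) NA_real_ else stats::sd(v)
    })
    z <- (x - m) / s
    z[!is.na(s) & s == 0] <- NA_real_
    if (any((is.na(s) | s == 0) & !is.na(x))) degenerate <- TRUE
    motor[[paste0(t, "_z")]] <- z
  }
  if (degenerate)
    warning("singleton or zero-variance strata produced missing z-scores")
  motor
}

#' Default two-year age categories for motor-test stratification
#'
#' @param age ages in years at the baseline test.
#' @param breaks lower edges of the bins; the last bin is open-ended
#'   (default `6-7`, `8-9`, `10-11`, `12+`, with children under the first
#'   edge folded into the first bin).
#' @return factor of age-category labels.
#' @export
motor_age_bin <- function(age, breaks = c(6, 8, 10, 12)) {
  labels <- c(paste(breaks[-length(breaks)],
                    breaks[-1] - 1, sep = "-"),
              paste0(breaks[length(breaks)], "+"))
  cut(pmax(age, breaks[1]), c(breaks, Inf), labels = labels, right = FALSE)
}

#' Motor-performance composite scores
#'
#' Arithmetic means of member z-scores: health-related fitness (hand grip,
#' Andersen test), coordination-related fitness (vertical jump, shuttle run,
#' backward balance, precision throw), and the total score over all six.
#' With `partial = TRUE` (default) a composite is the mean of whichever
#' members are present (missing when all are); `complete_only` marks rows
#' with any missing member instead.
#'
#' @param motor tibble with z-score columns `<test>_z`.
#' @param partial compute composites over available members?
#' @return `motor` with columns `health`, `coordination`, `total`, and
#'   `motor_complete` (all six z-scores present).
#' @export
composite_scores <- function(motor, partial = TRUE) {
  zcols <- paste0(motor_tests, "_z")
  stopifnot(all(zcols %in% names(motor)))
  z <- as.matrix(motor[zcols])
  mean_of <- function(cols) {
    m <- rowMeans(z[, paste0(cols, "_z"), drop = FALSE],
                  na.rm = partial)
    m[is.nan(m)] <- NA_real_
    m
  }
  motor$health <- mean_of(health_tests)
  motor$coordination <- mean_of(coordination_tests)
  motor$total <- mean_of(motor_tests)
  motor$motor_complete <- rowSums(is.na(z)) == 0L
  motor
}

#' Tertile labels for a composite score
#'
#' Cuts at the empirical 1/3 and 2/3 order-statistic quantiles (the sorted
#' values at positions `ceiling(n/3)` and `ceiling(2n/3)`): values at or
#' below the lower cut are `low`, at or below the upper cut `middle`, else
#' `high`. With distinct values and `n` divisible by 3 the groups are
#' equal-sized; ties at a cut are assigned downward, so tied data can give
#' unequal groups (all-equal values are all `low`).
#'
#' @param x numeric composite values (`NA` allowed, returned as `NA`).
#' @return factor with levels `low`, `middle`, `high`.
#' @export
tertile_assign <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 3) stop("need at least 3 non-missing values for tertiles")
  s <- sort(x[ok])
  n <- length(s)
  cut1 <- s[ceiling(n / 3)]
  cut2 <- s[ceiling(2 * n / 3)]
  out <- rep(NA_character_, length(x))
  out[ok] <- ifelse(x[ok] <= cut1, "low",
                    ifelse(x[ok] <= cut2, "middle", "high"))
  factor(out, levels = c("low", "middle", "high"))
}

#' Full motor-score pipeline
#'
#' Orientation, sex- and age-stratified z-scores, the three composites, and
#' tertiles of each composite, in one call.
#'
#' @param motor tibble with `child_id`, `test_age`, and the six raw test
#'   columns.
#' @param roster roster with `child_id` and `sex`.
#' @param age_breaks lower bin edges for [motor_age_bin()].
#' @return tibble with z-scores, composites, tertile labels
#'   (`total_tertile`, `health_tertile`, `coordination_tertile`) and the
#'   `motor_complete` flag.
#' @export
motor_score_pipeline <- function(motor, roster, age_breaks = c(6, 8, 10, 12)) {
  out <- motor |>
    dplyr::inner_join(roster[c("child_id", "sex")], by = "child_id") |>
    dplyr::mutate(age_bin = motor_age_bin(.data$test_age, age_breaks)) |>
    orient_scores() |>
    stratified_zscores() |>
    composite_scores()
  out$total_tertile <- tertile_assign(out$total)
  out$health_tertile <- tertile_assign(out$health)
  out$coordination_tertile <- tertile_assign(out$coordination)
  out
}
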