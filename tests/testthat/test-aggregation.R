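make_cal <- function() build_study_calendar("2010-01-01", "2010-12-31",
                                            integer(0))

test_that("monthly aggregation follows the sum-over-answered-weeks rule", {
  cal <- make_cal()
  # March 2010 has Mondays on the 1st, 8th, 15th, 22nd, 29th
  mar <- cal[format(cal$monday, "%m") == "03", ]
  mk <- function(sessions) tibble::tibble(
    child_id = "a",
    iso_year = mar$iso_year[seq_along(sessions)],
    iso_week = mar$iso_week[seq_along(sessions)],
    sessions = as.integer(sessions), sport_codes = "1"
  )
  roster <- roster_for("a", dob = as.Date("2002-03-15"))

  p1 <- aggregate_weekly_to_monthly(mk(c(2, 3, 4)), cal, roster)
  expect_equal(p1$y, 3.0)
  expect_equal(p1$n_weeks_observed, 3L)

  # two answered weeks or fewer -> missing
  p2 <- aggregate_weekly_to_monthly(mk(c(5, 6)), cal, roster)
  expect_true(is.na(p2$y))
  expect_equal(p2$n_weeks_observed, 2L)

  p3 <- aggregate_weekly_to_monthly(mk(c(0, 0, 7, 1)), cal, roster)
  expect_equal(p3$y, 2.0)

  # age in completed months on the first of the month (dob 2002-03-15)
  expect_equal(p1$age_months, 95L)
  expect_equal(p1$age, 95 / 12)
})

test_that("out-of-range session codes are dropped with a warning", {
  cal <- make_cal()
  wk <- tibble::tibble(child_id = "a", iso_year = 2010,
                       iso_week = c(10, 11, 12, 13),
                       sessions = c(2L, 9L, 3L, 4L), sport_codes = "1")
  expect_warning(
    p <- aggregate_weekly_to_monthly(wk, cal, roster_for("a")),
    "outside 0-8")
  expect_equal(sum(p$n_weeks_observed), 3L)
})

test_that("aggregation is order-invariant and constant counts pass through", {
  cal <- make_cal()
  wk <- constant_weekly(c("a", "b"), c(4, 0), cal)
  roster <- roster_for(c("a", "b"))
  p <- aggregate_weekly_to_monthly(wk, cal, roster)
  expect_true(all(p$y[p$child_id == "a" & !is.na(p$y)] == 4))
  expect_true(all(p$y[p$child_id == "b" & !is.na(p$y)] == 0))
  expect_true(all(p$y >= 0 & p$y <= 8, na.rm = TRUE))

  shuffled <- wk[sample.int(nrow(wk)), ]
  p2 <- aggregate_weekly_to_monthly(shuffled, cal, roster)
  expect_equal(p, p2)
})

test_that("children with fewer than two monthly values are excluded", {
  panel <- tibble::tibble(
    child_id = c("one", "one", "two", "two", "none", "none"),
    month = rep(as.Date(c("2010-01-01", "2010-02-01")), 3),
    y = c(3, NA, 2, 4, NA, NA)
  )
  ex <- exclude_sparse_children(panel)
  expect_setequal(ex$excluded, c("one", "none"))
  expect_setequal(unique(ex$panel$child_id), "two")

  all_sparse <- exclude_sparse_children(panel[panel$child_id != "two", ])
  expect_equal(nrow(all_sparse$panel), 0)
  expect_setequal(all_sparse$excluded, c("one", "none"))
})

test_that("sessions are split equally across reported sports", {
  wk <- tibble::tibble(child_id = "a", iso_year = 2010, iso_week = 1:3,
                       sessions = c(4L, 3L, 3L),
                       sport_codes = c("1;2", "1", "1;2"))
  al <- allocate_sport_sessions(wk)
  expect_equal(al$allocated[al$iso_week == 1], c(2, 2))
  expect_equal(al$allocated[al$iso_week == 2], 3)
  expect_equal(al$allocated[al$iso_week == 3], c(1.5, 1.5))
  # conservation
  expect_equal(sum(al$allocated), sum(wk$sessions))
})

test_that("sessions without a sport code go to 'other' with a warning", {
  wk <- tibble::tibble(child_id = "a", iso_year = 2010, iso_week = 1:2,
                       sessions = c(2L, 0L), sport_codes = c("", ""))
  expect_warning(al <- allocate_sport_sessions(wk), "other")
  expect_equal(al$sport, "other")
  expect_equal(al$allocated, 2)
})

test_that("session allocation conserves totals on random inputs", {
  set.seed(5)
  wk <- tibble::tibble(
    child_id = "a", iso_year = 2010, iso_week = 1:200,
    sessions = sample(1:8, 200, replace = TRUE),
    sport_codes = vapply(1:200, function(i)
      paste(sample(1:10, sample(1:3, 1)), collapse = ";"), character(1))
  )
  al <- allocate_sport_sessions(wk)
  expect_equal(sum(al$allocated), sum(wk$sessions), tolerance = 1e-10)
})

test_that("sport-type summary matches a hand-computed toy table", {
  wk <- tibble::tibble(
    child_id = c("a", "a", "b", "c"),
    iso_year = 2010, iso_week = c(1, 2, 1, 1),
    sessions = c(4L, 2L, 6L, 2L),
    sport_codes = c("1;2", "1", "7", "1;7")
  )
  asg <- tibble::tibble(child_id = c("a", "b", "c"),
                        group = c(1L, 1L, 2L))
  s <- sport_type_summary(wk, asg)
  # group 1: soccer 2+2+... child a: weeks (2 soccer + 2 handball) + 2
  # soccer; child b: 6 swimming -> totals: soccer 4, handball 2, swim 6
  g1 <- s[s$group == 1, ]
  expect_equal(g1$mean_sessions[g1$sport == "soccer"], 4 / 2)
  expect_equal(g1$mean_sessions[g1$sport == "handball"], 2 / 2)
  expect_equal(g1$mean_sessions[g1$sport == "swimming"], 6 / 2)
  expect_equal(g1$pct[g1$sport == "soccer"], 100 * 4 / 12)
  # single child, two equal sports -> 50/50
  g2 <- s[s$group == 2, ]
  expect_equal(sort(g2$pct), c(50, 50))
  # percentages sum to 100 within each group
  expect_equal(as.numeric(tapply(s$pct, s$group, sum)), c(100, 100),
               tolerance = 0.1)
  # unknown children are an error
  expect_error(sport_type_summary(wk, asg[-1, ]), "no trajectory group")
})
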