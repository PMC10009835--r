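#' Configuration of a synthetic sports-participation cohort
#'
#' Collects every knob of the open-cohort simulator. The defaults emulate
#' the structure of a Danish school cohort followed for five school years:
#' roughly 1,500 children entering at ages 5--13, weekly prompts suspended
#' over Christmas and a six-week summer break, integer weekly session counts
#' censored at 0 and 8, five latent trajectory groups with polynomial age
#' trends (from a stable near-zero group to a steeply increasing one),
#' non-response on some weeks, gradual dropout with late entry, and six
#' baseline motor-performance tests shifted by group through a single
#' latent fitness factor.
#'
#' @param n_children cohort size.
#' @param entry_age_range ages (years) at study entry, sampled uniformly.
#' @param study_start,study_end first and last month of follow-up.
#' @param membership_logits per-group membership log-odds (group 1 = 0 is
#'   the reference); group shares are `softmax` of these.
#' @param beta matrix (`G x 4`) of cubic coefficients of the latent weekly
#'   mean on the scaled age axis of `age_range`.
#' @param sigma residual SD of the latent weekly value (sessions/week).
#' @param age_range ages mapped to `[-1, 1]` for the polynomials.
#' @param weekly_response_rate probability a prompted week is answered.
#' @param dropout_hazard per-month probability of leaving the study.
#' @param late_entry_fraction share of children entering after baseline,
#'   uniformly over the first three follow-up years.
#' @param motor_effects per-group shift (SD units) of the latent fitness
#'   factor behind the six motor tests.
#' @param holiday_weeks ISO weeks with no prompt (see
#'   [build_study_calendar()]).
#' @param rng_seed integer seed making the whole cohort reproducible.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_children = 1500,
    entry_age_range = c(5, 13),
    study_start = "2009-08-01",
    study_end = "2014-06-30",
    membership_logits = c(0, 0.693, 0.765, 0.488, -0.451),
    beta = NULL,
    sigma = 1.5,
    age_range = c(6, 16),
    weekly_response_rate = 0.8,
    dropout_hazard = 0.005,
    late_entry_fraction = 0.15,
    motor_effects = NULL,
    holiday_weeks = c(52L, 53L, 1L, 27:32),
    rng_seed = 1L) {
  G <- length(membership_logits)
  if (is.null(beta)) beta <- default_trajectory_beta(G)
  beta <- matrix(beta, nrow = G)
  stopifnot(G >= 1L, ncol(beta) == 4L, sigma > 0,
            weekly_response_rate >= 0, weekly_response_rate <= 1,
            dropout_hazard >= 0, dropout_hazard <= 1,
            all(is.finite(membership_logits)),
            n_children >= 0)
  if (is.null(motor_effects))
    motor_effects <- if (G == 1L) 0 else seq(-0.6, 0.6, length.out = G)
  stopifnot(length(motor_effects) == G)
  structure(
    list(n_children = as.integer(n_children),
         entry_age_range = entry_age_range,
         study_start = as.Date(study_start), study_end = as.Date(study_end),
         membership_logits = membership_logits, beta = beta, sigma = sigma,
         age_range = age_range,
         weekly_response_rate = weekly_response_rate,
         dropout_hazard = dropout_hazard,
         late_entry_fraction = late_entry_fraction,
         motor_effects = motor_effects, holiday_weeks = holiday_weeks,
         rng_seed = as.integer(rng_seed)),
    class = "cohort_config"
  )
}

# Default latent mean curves on the scaled age axis: the canonical
# five-group pattern (stable near-zero, low decreasing, three increasing at
# different rates with a late easing). Other G pick evenly spaced shapes.
default_trajectory_beta <- function(G) {
  canon <- rbind(
    c(-0.8,  0.0,  0.0,  0.0),   # stable, little to no participation
    c( 1.2, -1.0,  0.0,  0.0),   # low, decreasing
    c( 2.0,  1.2, -0.6,  0.0),   # low-moderate, slightly increasing
    c( 2.8,  1.8, -0.8,  0.0),   # moderate, increasing then easing
    c( 3.2,  3.0,  0.0, -2.5)    # high, rapidly increasing then easing
  )
  canon[round(seq(1, 5, length.out = G)), , drop = FALSE]
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Sport-type codes 1..10 and community popularity weights used to hand each
# child a static set of one or two sports.
sport_names <- c("soccer", "handball", "basketball", "volleyball",
                 "rhythmic_gymnastics", "tumbling_gymnastics", "swimming",
                 "horse_riding", "dancing", "other")
sport_weights <- c(0.30, 0.21, 0.02, 0.07, 0.03, 0.02, 0.08, 0.09, 0.03, 0.15)

#' Generate a synthetic open cohort of weekly sports reports
#'
#' Draws a full synthetic study: a child roster (sex, school type, date of
#' birth, entry and exit months), weekly SMS-style responses (integer
#' session counts 0--8, with 8 coding "more than seven", plus reported sport
#' types), baseline motor-performance tests, and the ground truth needed for
#' recovery experiments.
#'
#' Each child's latent weekly value is their group's cubic age polynomial
#' plus `Normal(0, sigma)` noise; the observed count is the latent value
#' rounded and clipped to `[0, 8]`. Weeks outside the child's enrolment,
#' holiday weeks, and non-answered weeks are absent. Motor tests load on a
#' single latent fitness factor shifted by group; the shuttle run is
#' generated so that a smaller time is better.
#'
#' @param config a [cohort_config()].
#' @return list with `roster`, `weekly`, `motor`, and `truth` (a list with
#'   the per-child true group, the per-week latent values, and the config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$rng_seed)
  n <- config$n_children
  calendar <- build_study_calendar(config$study_start, config$study_end,
                                   config$holiday_weeks)
  months <- seq(lubridate::floor_date(config$study_start, "month"),
                lubridate::floor_date(config$study_end, "month"),
                by = "month")
  empty <- list(
    roster = tibble::tibble(child_id = character(), sex = character(),
                            school_type = character(), school = character(),
                            dob = as.Date(character()),
                            entry_month = as.Date(character()),
                            exit_month = as.Date(character())),
    weekly = tibble::tibble(child_id = character(), iso_year = integer(),
                            iso_week = integer(), sessions = integer(),
                            sport_codes = character()),
    motor = tibble::tibble(child_id = character()),
    truth = list(group = tibble::tibble(child_id = character(),
                                        group = integer()),
                 latent = NULL, config = config)
  )
  if (n == 0L) return(empty)

  G <- length(config$membership_logits)
  pi <- softmax(config$membership_logits)
  ids <- sprintf("c%04d", seq_len(n))
  sex <- sample(c("girl", "boy"), n, replace = TRUE, prob = c(0.516, 0.484))
  school <- sample(sprintf("school%02d", 1:10), n, replace = TRUE)
  school_type <- ifelse(as.integer(sub("school", "", school)) <= 6,
                        "sports", "control")
  group <- sample.int(G, n, replace = TRUE, prob = pi)

  late <- stats::runif(n) < config$late_entry_fraction
  entry_month <- rep(months[1], n)
  n_entry_window <- min(36L, length(months))
  entry_month[late] <- months[sample.int(n_entry_window, sum(late),
                                         replace = TRUE)]
  entry_age <- stats::runif(n, config$entry_age_range[1],
                            config$entry_age_range[2])
  dob <- entry_month - round(entry_age * 365.25) -
    sample.int(28L, n, replace = TRUE)

  # geometric follow-up under a constant per-month dropout hazard
  months_left <- vapply(entry_month, function(e) sum(months >= e),
                        integer(1))
  stay <- if (config$dropout_hazard > 0)
    stats::rgeom(n, config$dropout_hazard) + 1L else months_left
  entry_idx <- match(entry_month, months)
  exit_idx <- pmin(entry_idx + pmin(stay, months_left) - 1L, length(months))
  exit_month <- months[exit_idx]

  roster <- tibble::tibble(
    child_id = ids, sex = sex, school_type = school_type, school = school,
    dob = dob, entry_month = entry_month, exit_month = exit_month
  )

  # one or two static sports per child
  n_sports <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
  sports <- lapply(seq_len(n), function(i)
    sort(sample.int(10L, n_sports[i], prob = sport_weights)))

  # weekly responses: cross enrolment with the prompt calendar
  wk <- vector("list", n)
  for (i in seq_len(n)) {
    in_window <- calendar$month >= entry_month[i] &
      calendar$month <= exit_month[i]
    if (!any(in_window)) next
    cal_i <- calendar[in_window, , drop = FALSE]
    age <- as.numeric(cal_i$monday - dob[i]) / 365.25
    a <- (age - mean(config$age_range)) / (diff(config$age_range) / 2)
    mu <- drop(outer(a, 0:3, `^`) %*% config$beta[group[i], ])
    latent <- mu + stats::rnorm(nrow(cal_i), 0, config$sigma)
    sessions <- pmin(pmax(round(latent), 0), 8)
    answered <- stats::runif(nrow(cal_i)) < config$weekly_response_rate
    if (!any(answered)) next
    codes <- ifelse(sessions[answered] >= 1L,
                    paste(sports[[i]], collapse = ";"), "")
    wk[[i]] <- tibble::tibble(
      child_id = ids[i],
      iso_year = cal_i$iso_year[answered],
      iso_week = cal_i$iso_week[answered],
      sessions = as.integer(sessions[answered]),
      sport_codes = codes,
      latent = latent[answered]
    )
  }
  weekly <- dplyr::bind_rows(wk)

  motor <- generate_motor_tests(roster, group, config)

  truth <- list(
    group = tibble::tibble(child_id = ids, group = group),
    latent = weekly[c("child_id", "iso_year", "iso_week", "latent")],
    config = config
  )
  weekly$latent <- NULL
  list(roster = roster, weekly = weekly, motor = motor, truth = truth)
}

# Six baseline motor tests from one latent fitness factor. Group shifts
# enter through the factor only, inducing a monotone gradient across all
# tests; the shuttle run gets a negative loading (smaller time = better).
generate_motor_tests <- function(roster, group, config) {
  n <- nrow(roster)
  age <- as.numeric(roster$entry_month - roster$dob) / 365.25
  boy <- roster$sex == "boy"
  f <- config$motor_effects[group] + stats::rnorm(n, 0, 1)
  d <- age - 6
  tibble::tibble(
    child_id = roster$child_id,
    test_age = age,
    balance = pmin(pmax(round(30 + 3.0 * d + 2 * boy + 6 * f +
                                stats::rnorm(n, 0, 5)), 0), 72),
    throw = pmin(pmax(round(10 + 1.5 * d + 1.5 * boy + 2.5 * f +
                              stats::rnorm(n, 0, 2.5)), 0), 30),
    grip = round(9 + 2.2 * d + 1.5 * boy + 2 * f +
                   stats::rnorm(n, 0, 2), 1),
    jump = round(18 + 1.8 * d + 2 * boy + 3 * f + stats::rnorm(n, 0, 3), 1),
    shuttle = round(26 - 0.8 * d - 0.8 * boy - 1.5 * f +
                      stats::rnorm(n, 0, 1.5), 2),
    andersen = round(820 + 28 * d + 25 * boy + 45 * f +
                       stats::rnorm(n, 0, 60))
  )
}

#' Generate a panel drawn exactly from the censored-normal model
#'
#' Unlike [generate_cohort()] (which rounds weekly counts to integers before
#' monthly averaging), this draws each monthly value directly from the
#' censored-normal observation model at the design ages: latent
#' `Normal(mu_g(age), sigma^2)` clipped to the censoring limits, with no
#' rounding. Used for clean parameter-recovery experiments.
#'
#' @param params a [gbtm_params()] holding the generating spec, `beta`,
#'   `sigma` and membership probabilities.
#' @param ages age grid (years) at which every child is observed; must lie
#'   inside the spec's `age_range`.
#' @param n_children number of children.
#' @param seed integer seed.
#' @param missing_rate MCAR probability that an observation is missing.
#' @return list with `panel` (tibble `child_id`, `age`, `y`) and `truth`
#'   (tibble `child_id`, `group`).
#' @export
generate_model_faithful_panel <- function(params, ages, n_children,
                                          seed = 1, missing_rate = 0) {
  stopifnot(inherits(params, "gbtm_params"))
  spec <- params$spec
  if (any(ages < spec$age_range[1] - 1e-9 | ages > spec$age_range[2] + 1e-9))
    stop("design ages outside the spec's age range")
  set.seed(as.integer(seed))
  n <- as.integer(n_children)
  group <- sample.int(spec$G, n, replace = TRUE, prob = params$pi)
  X <- poly_basis(spec, ages)
  mu <- X %*% t(params$beta)                 # ages x G
  m <- length(ages)
  latent <- mu[, group] + matrix(stats::rnorm(m * n, 0, params$sigma), m, n)
  y <- pmin(pmax(latent, spec$y_min), spec$y_max)
  if (missing_rate > 0)
    y[stats::runif(m * n) < missing_rate] <- NA_real_
  ids <- sprintf("c%04d", seq_len(n))
  panel <- tibble::tibble(
    child_id = rep(ids, each = m),
    age = rep(ages, times = n),
    y = as.vector(y)
  )
  list(panel = panel, truth = tibble::tibble(child_id = ids, group = group))
}
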