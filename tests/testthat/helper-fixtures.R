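# Shared fixtures, all built in code.

# Well-separated three-group generating parameters used by the recovery and
# cross-validation experiments.
separated_params_3g <- function(sigma = 1) {
  spec <- trajectory_spec(3, order = 3, age_range = c(6, 16))
  gbtm_params(
    spec,
    beta = rbind(c(0.5, -0.2, 0, 0),
                 c(3.0,  1.5, 0, 0),
                 c(6.0,  1.0, 0, 0)),
    sigma = sigma,
    theta = log(c(0.4, 0.3) / 0.3)   # pi = (0.3, 0.4, 0.3)
  )
}

# A tiny deterministic panel: 2 children, a few months each, values away
# from the censoring limits.
toy_panel <- function() {
  tibble::tibble(
    child_id = c("a", "a", "a", "b", "b"),
    age = c(8, 9, 10, 8.5, 9.5),
    y = c(2.0, 2.5, 3.0, 5.0, 5.5)
  )
}

# Weekly fixture with known monthly aggregates: all weeks of one calendar
# year for children on fixed weekly counts.
constant_weekly <- function(ids, counts, calendar) {
  dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    tibble::tibble(
      child_id = ids[i],
      iso_year = calendar$iso_year,
      iso_week = calendar$iso_week,
      sessions = as.integer(counts[i]),
      sport_codes = ifelse(counts[i] >= 1, "1", "")
    )
  }))
}

roster_for <- function(ids, dob = as.Date("2000-01-01"),
                       entry = NULL, exit = NULL) {
  r <- tibble::tibble(child_id = ids, dob = dob,
                      sex = rep_len(c("girl", "boy"), length(ids)))
  if (!is.null(entry)) {
    r$entry_month <- entry
    r$exit_month <- exit
  }
  r
}

# Individual-level data from a group x tertile contingency table.
expand_counts <- function(tab) {
  idx <- which(tab > 0, arr.ind = TRUE)
  data.frame(
    group = rep(rownames(tab)[idx[, 1]], tab[idx]),
    tertile = rep(colnames(tab)[idx[, 2]], tab[idx])
  )
}
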