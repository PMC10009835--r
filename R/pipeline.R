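#' Run the full trajectory analysis pipeline
#'
#' Orchestrates the stages end-to-end on a simulated cohort: generate
#' weekly reports, aggregate them to the monthly panel, fit trajectory
#' models over a range of group counts with selection diagnostics and
#' cross-validation, pick a model, compute motor-performance composites,
#' and regress group membership on sex, school type and motor tertiles
#' with cluster-robust variance. All artifacts are plain CSV/JSON in
#' `out_dir`, plus a manifest recording the seed and settings, so any stage
#' can be rerun standalone.
#'
#' @param config list with optional elements `cohort` (arguments to
#'   [cohort_config()]), `G_range` (default `1:5`), `cv_k` (fold counts,
#'   default `c(2, 10)`; `NULL` skips CV), `age_breaks` (motor-score bins),
#'   `cluster` (`"school"`), `n_starts`, `seed`.
#' @param out_dir output directory (created if needed); `NULL` returns
#'   results without writing files.
#' @return invisible list with every stage's result (`cohort`, `panel`,
#'   `selection`, `chosen_G`, `fit`, `trajectories`, `scores`,
#'   `association`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  t0 <- Sys.time()
  seed <- config$seed %||% 1L
  G_range <- config$G_range %||% 1:5
  cv_k <- if ("cv_k" %in% names(config)) config$cv_k else c(2, 10)
  n_starts <- config$n_starts %||% 3L
  cohort_args <- config$cohort %||% list()
  cohort_args$rng_seed <- seed
  cfg <- do.call(cohort_config, cohort_args)

  # 1. simulate
  cohort <- generate_cohort(cfg)

  # 2. aggregate weekly reports to the monthly panel
  calendar <- build_study_calendar(cfg$study_start, cfg$study_end,
                                   cfg$holiday_weeks)
  panel_all <- aggregate_weekly_to_monthly(cohort$weekly, calendar,
                                           cohort$roster)
  excl <- exclude_sparse_children(panel_all)
  panel <- excl$panel

  # 3. model selection
  sel <- selection_table(panel, G_range, cv_k = cv_k, seed = seed,
                         n_starts = n_starts)
  chosen_G <- choose_group_count(sel)
  fit <- sel$fits[[as.character(chosen_G)]]

  # 4. trajectory curves with bands
  trajectories <- predict_trajectory(fit)

  # 5. motor scores
  scores <- motor_score_pipeline(cohort$motor, cohort$roster,
                                 config$age_breaks %||% c(6, 8, 10, 12))

  # 6. association of group membership with covariates
  assignments <- tibble::tibble(child_id = fit$child_ids,
                                group = fit$assignment)
  adat <- assignments |>
    dplyr::inner_join(cohort$roster, by = "child_id") |>
    dplyr::inner_join(
      scores[c("child_id", "total_tertile", "motor_complete")],
      by = "child_id") |>
    dplyr::filter(.data$motor_complete)
  association <- NULL
  if (nrow(adat) > 0 && length(unique(adat$group)) >= 2) {
    outcome <- factor(adat$group)
    design <- data.frame(
      sex = stats::relevel(factor(adat$sex), "girl"),
      school_type = stats::relevel(factor(adat$school_type), "control"),
      total = factor(adat$total_tertile, c("low", "middle", "high"))
    )
    afit <- fit_multinomial(outcome, design)
    vc <- cluster_robust_vcov(afit, adat[[config$cluster %||% "school"]])
    null_fit <- fit_multinomial(outcome,
                                data.frame(row.names = seq_along(outcome)))
    association <- list(
      fit = afit,
      rrr = rrr_table(afit, vc),
      overall = overall_test(afit, null_fit)
    )
  }

  # 7. group descriptives (sizes, sport profile)
  descriptives <- assignments |>
    dplyr::count(.data$group, name = "n_children")
  sport_profile <- sport_type_summary(
    cohort$weekly[cohort$weekly$child_id %in% assignments$child_id, ],
    assignments)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sporttraj")),
    seed = seed, G_range = G_range, cv_k = cv_k, chosen_G = chosen_G,
    n_children_simulated = cfg$n_children,
    n_children_analysed = fit$n_children,
    n_obs = fit$n_obs,
    excluded_children = length(excl$excluded),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  res <- list(cohort = cohort, panel = panel, selection = sel,
              chosen_G = chosen_G, fit = fit, trajectories = trajectories,
              scores = scores, association = association,
              descriptives = descriptives, sport_profile = sport_profile,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pick the number of groups from a selection table
#'
#' Encodes the pragmatic selection rule: among candidates, prefer the smallest
#' G at which the cross-validated mean distance has stabilised (within
#' `cv_tol` relative of the best achieved) while all groups remain adequate
#' (APPA/OCC/minimum-size flags); without CV columns, the best
#' children-level BIC among adequate candidates wins.
#'
#' @param sel a [selection_table()] result.
#' @param cv_tol relative tolerance for "stabilised" (default 0.02).
#' @return the chosen number of groups.
#' @export
choose_group_count <- function(sel, cv_tol = 0.02) {
  tab <- sel$table[!is.na(sel$table$loglik), , drop = FALSE]
  if (nrow(tab) == 0) stop("no successful fits to choose from")
  cand <- tab[tab$adequate %in% TRUE, , drop = FALSE]
  if (nrow(cand) == 0) cand <- tab
  cv_cols <- grep("^cv_", names(tab), value = TRUE)
  if (length(cv_cols)) {
    cv <- rowMeans(as.matrix(cand[cv_cols]), na.rm = TRUE)
    best <- min(cv)
    ok <- cv <= best * (1 + cv_tol)
    cand$G[which(ok)[1]]
  } else {
    cand$G[which.max(cand$bic_children)]
  }
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name)
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  wcsv(res$selection$table, "selection_table.csv")
  cv_cols <- grep("^cv_", names(res$selection$table), value = TRUE)
  if (length(cv_cols))
    wcsv(res$selection$table[c("G", cv_cols)], "cv_distance.csv")
  wcsv(res$trajectories, "trajectories.csv")
  wcsv(res$panel, "monthly_panel.csv")
  wcsv(res$descriptives, "group_sizes.csv")
  wcsv(res$sport_profile, "sport_profile.csv")
  wcsv(res$scores, "motor_scores.csv")
  if (!is.null(res$association)) {
    wcsv(res$association$rrr, "association_rrr.csv")
    jsonlite::write_json(res$association$overall,
                         file.path(out_dir, "association_overall.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
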