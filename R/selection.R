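#' Information criteria in the trajectory-software convention
#'
#' `AIC = l - k` and `BIC_n = l - (k/2) ln n`, reported so that larger is
#' better, evaluated at both the number of observations and the number of
#' children (the two sample sizes relevant to a longitudinal mixture).
#'
#' @param loglik maximised log-likelihood.
#' @param k number of free parameters (see [count_parameters()]).
#' @param n_obs number of non-missing observations.
#' @param n_children number of children.
#' @return named list with `aic`, `bic_obs`, `bic_children`.
#' @export
information_criteria <- function(loglik, k, n_obs, n_children) {
  if (k < 0) stop("`k` must be non-negative")
  stopifnot(n_obs >= n_children, n_children >= 1)
  list(
    aic = loglik - k,
    bic_obs = loglik - (k / 2) * log(n_obs),
    bic_children = loglik - (k / 2) * log(n_children)
  )
}

#' Average posterior probability of assignment (APPA)
#'
#' For each group, the mean posterior membership probability among the
#' children modally assigned to it. Values near 1 indicate clean separation;
#' the usual adequacy threshold is 0.7.
#'
#' @param fit a [fit_gbtm()] result (or any list with elements `w` and
#'   `assignment`).
#' @return numeric vector of length G; `NA` for empty groups.
#' @export
appa <- function(fit) {
  G <- ncol(fit$w)
  vapply(seq_len(G), function(j) {
    in_j <- fit$assignment == j
    if (!any(in_j)) NA_real_ else mean(fit$w[in_j, j])
  }, numeric(1))
}

#' Odds of correct classification (OCC)
#'
#' Ratio of the posterior assignment odds to the prior (estimated share)
#' odds, per group: `OCC_j = [APPA_j/(1-APPA_j)] / [pi_j/(1-pi_j)]`. Values
#' above 5 indicate assignment much better than chance. Undefined for a
#' one-group model (returns `NA`); `APPA_j = 1` gives `Inf`.
#'
#' @param fit a [fit_gbtm()] result.
#' @return numeric vector of length G.
#' @export
occ <- function(fit) {
  G <- ncol(fit$w)
  if (G == 1L) return(NA_real_)
  ap <- appa(fit)
  pi <- fit$params$pi
  ifelse(is.na(ap), NA_real_,
         (ap / (1 - ap)) / (pi / (1 - pi)))
}

# Mean prediction distance for a set of held-out children under a trained
# model. Per observation: a weighted mean absolute distance between the
# observed value and each group's expected observed curve. Weights are the
# held-out child's own posteriors under the trained model ("posterior"),
# a 0/1 modal version ("modal"), or the trained shares pi ("marginal").
holdout_distance <- function(fit_params, holdout_panel,
                             method = c("posterior", "modal", "marginal")) {
  method <- match.arg(method)
  spec <- fit_params$spec
  pp <- prepare_panel(holdout_panel, spec)
  mu <- pp$X %*% t(fit_params$beta)
  curves <- apply(mu, 2, cnorm_expected_observed, sigma = fit_params$sigma,
                  y_min = spec$y_min, y_max = spec$y_max)
  curves <- matrix(curves, nrow = pp$n_obs)
  absd <- abs(pp$y - curves)               # n_obs x G
  if (method == "marginal") {
    wobs <- matrix(fit_params$pi, pp$n_obs, spec$G, byrow = TRUE)
  } else {
    w <- posterior_probs(holdout_panel, fit_params)
    if (method == "modal") {
      mo <- max.col(w, ties.method = "first")
      w <- matrix(0, nrow(w), ncol(w))
      w[cbind(seq_len(nrow(w)), mo)] <- 1
    }
    wobs <- w[pp$idx, , drop = FALSE]
  }
  list(sum = sum(wobs * absd), n = pp$n_obs,
       mean = sum(wobs * absd) / pp$n_obs)
}

#' Child-level k-fold cross-validated prediction distance
#'
#' Randomly splits the children (not the observations) into `k` folds once,
#' refits the model on each training set, and scores every held-out child's
#' observations by the posterior-weighted mean absolute distance to the
#' trained group curves (the held-out child's posteriors are computed from
#' their own data under the trained model). Returns the mean over all
#' held-out observations; deterministic given `seed`.
#'
#' @param panel monthly panel (`child_id`, `age`, `y`).
#' @param G number of groups.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the single random split and the fold fits.
#' @param spec optional [trajectory_spec()] shared by all folds.
#' @param method weighting of group curves: `"posterior"` (default),
#'   `"modal"`, or `"marginal"`.
#' @param n_starts,max_iter,tol EM settings for the fold fits.
#' @return list with `mean_distance`, `per_fold`, `k`, `method`.
#' @export
kfold_cv <- function(panel, G, k, seed = 1, spec = NULL,
                     method = "posterior", n_starts = 2, max_iter = 200,
                     tol = 1e-6) {
  keep <- !is.na(panel$y)
  ids <- sort(unique(panel$child_id[keep]))
  n <- length(ids)
  if (k < 2) stop("`k` must be at least 2")
  if (k > n) stop("more folds than children")
  if (is.null(spec)) {
    rng <- range(panel$age[keep])
    spec <- trajectory_spec(G, age_range = rng)
  }
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), n))
  if (any(tabulate(fold, k) == 0L)) stop("a fold received zero children")
  tot <- 0
  nobs <- 0
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    test_ids <- ids[fold == f]
    train <- panel[panel$child_id %in% setdiff(ids, test_ids), , drop = FALSE]
    test <- panel[panel$child_id %in% test_ids, , drop = FALSE]
    fit <- fit_gbtm(train, spec = spec, n_starts = n_starts,
                    seed = seed + f, max_iter = max_iter, tol = tol)
    d <- holdout_distance(fit$params, test, method = method)
    per_fold[f] <- d$mean
    tot <- tot + d$sum
    nobs <- nobs + d$n
  }
  list(mean_distance = tot / nobs, per_fold = per_fold, k = k,
       method = method)
}

#' Leave-one-out cross-validated prediction distance
#'
#' [kfold_cv()] with one child per fold; each child is left out in turn, so
#' there is no randomness in the split. Intended for small cohorts (it
#' refits the model once per child).
#'
#' @inheritParams kfold_cv
#' @return list as in [kfold_cv()].
#' @export
loo_cv <- function(panel, G, spec = NULL, method = "posterior",
                   n_starts = 2, max_iter = 200, seed = 1, tol = 1e-6) {
  n <- length(unique(panel$child_id[!is.na(panel$y)]))
  kfold_cv(panel, G, k = n, seed = seed, spec = spec, method = method,
           n_starts = n_starts, max_iter = max_iter, tol = tol)
}

#' Model-selection table over a range of group counts
#'
#' Fits the trajectory model for each candidate number of groups and
#' assembles the selection diagnostics: parameter count, AIC, BIC on
#' observations and on children, minimum APPA and OCC across groups, the
#' smallest modal group, and (optionally) cross-validated mean distances.
#' Groups failing the adequacy rules (APPA > 0.7, OCC > 5, minimum size)
#' are flagged rather than dropped. A fit failure for one G is recorded as
#' an `NA` row and does not abort the table.
#'
#' @param panel monthly panel (`child_id`, `age`, `y`).
#' @param G_range candidate group counts, e.g. `1:6`.
#' @param cv_k numeric vector of fold counts for cross-validation (use
#'   `Inf` for leave-one-out); `NULL` skips CV.
#' @param seed integer seed for fits and CV splits.
#' @param order polynomial degree (default cubic).
#' @param appa_min,occ_min,size_min adequacy thresholds (defaults 0.7, 5,
#'   and 1% of children).
#' @param n_starts,max_iter,tol EM settings for the headline fits.
#' @param cv_n_starts EM starts for the (cheaper) fold fits.
#' @return list with `table` (a tibble, one row per G) and `fits` (the
#'   successful [fit_gbtm()] objects, named by G).
#' @export
selection_table <- function(panel, G_range, cv_k = NULL, seed = 1,
                            order = 3, appa_min = 0.7, occ_min = 5,
                            size_min = NULL, n_starts = 3, max_iter = 500,
                            tol = 1e-6, cv_n_starts = 1) {
  keep <- !is.na(panel$y)
  rng <- range(panel$age[keep])
  n_children <- length(unique(panel$child_id[keep]))
  if (is.null(size_min)) size_min <- max(1, round(0.01 * n_children))

  fits <- list()
  rows <- vector("list", length(G_range))
  for (i in seq_along(G_range)) {
    G <- G_range[i]
    spec <- trajectory_spec(G, order = order, age_range = rng)
    fit <- tryCatch(
      fit_gbtm(panel, spec = spec, n_starts = n_starts, seed = seed,
               max_iter = max_iter, tol = tol),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      rows[[i]] <- tibble::tibble(G = G, k = count_parameters(spec),
                                  loglik = NA_real_, aic = NA_real_,
                                  bic_obs = NA_real_, bic_children = NA_real_,
                                  appa_min = NA_real_, occ_min = NA_real_,
                                  min_group_size = NA_integer_,
                                  adequate = NA)
      next
    }
    fits[[as.character(G)]] <- fit
    ic <- information_criteria(fit$loglik, count_parameters(spec),
                               fit$n_obs, fit$n_children)
    ap <- appa(fit)
    oc <- occ(fit)
    sizes <- tabulate(fit$assignment, G)
    adequate <- all(ap > appa_min, na.rm = FALSE) &&
      (G == 1L || all(oc > occ_min)) && min(sizes) >= size_min
    row <- tibble::tibble(
      G = G, k = count_parameters(spec), loglik = fit$loglik,
      aic = ic$aic, bic_obs = ic$bic_obs, bic_children = ic$bic_children,
      appa_min = min(ap), occ_min = if (G == 1L) NA_real_ else min(oc),
      min_group_size = min(sizes), adequate = adequate
    )
    if (!is.null(cv_k)) {
      for (kk in cv_k) {
        cvres <- if (is.infinite(kk))
          loo_cv(panel, G, spec = spec, seed = seed,
                 n_starts = cv_n_starts, max_iter = max_iter, tol = tol)
        else
          kfold_cv(panel, G, k = kk, seed = seed, spec = spec,
                   n_starts = cv_n_starts, max_iter = max_iter, tol = tol)
        nm <- if (is.infinite(kk)) "cv_loo" else paste0("cv_", kk)
        row[[nm]] <- cvres$mean_distance
      }
    }
    rows[[i]] <- row
  }
  list(table = dplyr::bind_rows(rows), fits = fits,
       thresholds = list(appa_min = appa_min, occ_min = occ_min,
                         size_min = size_min))
}
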