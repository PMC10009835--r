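# Mixture log-likelihood as a function of the packed parameter vector
# c(vec(beta), log sigma, theta); used for the numerical Hessian behind
# delta-method bands.
mixture_ll_par <- function(par, pp, spec) {
  G <- spec$G
  p <- spec$order + 1L
  beta <- matrix(par[seq_len(G * p)], nrow = G)
  sigma <- exp(par[G * p + 1L])
  theta <- if (G > 1L) par[(G * p + 2L):(G * p + G)] else numeric(0)
  lp <- c(0, theta)
  lpi <- lp - log(sum(exp(lp - max(lp)))) - max(lp)
  ld <- obs_log_density(pp, beta, sigma, spec)
  llmat <- rowsum(ld, pp$idx, reorder = TRUE)
  sum(log_row_sum_exp(sweep(llmat, 2, lpi, `+`)))
}

pack_params <- function(params) {
  c(as.vector(params$beta), log(params$sigma), params$theta)
}

#' Covariance of the fitted trajectory parameters
#'
#' Inverse of the numerical observed-information matrix of the mixture
#' log-likelihood at the fitted maximum, on the internal parameterisation
#' (polynomial coefficients, log sigma, membership logits).
#'
#' @param fit a [fit_gbtm()] result.
#' @return covariance matrix of the packed parameter vector.
#' @export
gbtm_vcov <- function(fit) {
  spec <- fit$params$spec
  pp <- fit$data
  par <- pack_params(fit$params)
  H <- stats::optimHess(par, function(p) -mixture_ll_par(p, pp, spec))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V))) {
    # near-singular information (e.g. empty group): ridge fallback
    V <- solve(H + diag(1e-6 * (abs(diag(H)) + 1)))
  }
  (V + t(V)) / 2
}

#' Predicted group trajectories on the observed scale
#'
#' Expected observed outcome of each trajectory group over an age grid,
#' with point-wise delta-method confidence bands. The curve is the mean of
#' the censored-normal observation model, so it always lies inside the
#' censoring limits even when the latent polynomial does not.
#'
#' @param fit a [fit_gbtm()] result.
#' @param ages age grid in years (default: 50 points over the fitted range).
#' @param level band coverage (default 0.95).
#' @param se compute bands? (set `FALSE` to skip the Hessian).
#' @param vcov optional precomputed [gbtm_vcov()] matrix.
#' @return tibble with columns `group`, `age`, `mean`, and (with `se`)
#'   `lower`, `upper`, all clipped to the censoring limits.
#' @export
predict_trajectory <- function(fit, ages = NULL, level = 0.95, se = TRUE,
                               vcov = NULL) {
  spec <- fit$params$spec
  if (is.null(ages))
    ages <- seq(fit$panel_age_range[1], fit$panel_age_range[2],
                length.out = 50)
  if (any(ages < fit$panel_age_range[1] - 1e-9 |
            ages > fit$panel_age_range[2] + 1e-9))
    warning("extrapolating outside the fitted age range")
  G <- spec$G
  p <- spec$order + 1L
  X <- poly_basis(spec, ages)
  beta <- fit$params$beta
  sigma <- fit$params$sigma
  npar <- G * p + 1L + (G - 1L)

  if (se && is.null(vcov)) vcov <- gbtm_vcov(fit)

  rows <- vector("list", G)
  for (j in seq_len(G)) {
    mu <- as.vector(X %*% beta[j, ])
    est <- cnorm_expected_observed(mu, sigma, spec$y_min, spec$y_max)
    out <- tibble::tibble(group = j, age = ages, mean = est)
    if (se) {
      a <- (spec$y_min - mu) / sigma
      b <- (spec$y_max - mu) / sigma
      dmu <- stats::pnorm(b) - stats::pnorm(a)     # dE/dmu
      dls <- sigma * (stats::dnorm(a) - stats::dnorm(b))  # dE/dlog sigma
      sevec <- vapply(seq_along(ages), function(i) {
        g <- numeric(npar)
        g[(seq_len(p) - 1L) * G + j] <- dmu[i] * X[i, ]  # beta_j entries
        g[G * p + 1L] <- dls[i]
        sqrt(max(0, drop(t(g) %*% vcov %*% g)))
      }, numeric(1))
      z <- stats::qnorm(1 - (1 - level) / 2)
      out$lower <- pmax(est - z * sevec, spec$y_min)
      out$upper <- pmin(est + z * sevec, spec$y_max)
    }
    rows[[j]] <- out
  }
  dplyr::bind_rows(rows)
}
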