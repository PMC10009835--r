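#' Censored-normal log density
#'
#' Log-likelihood contribution of one observation under the censored-normal
#' (Tobit-type) observation model used for weekly sports-session counts: a
#' latent normal value with mean `mu` and SD `sigma` is observed exactly
#' inside `[y_min, y_max]` and piled as point masses at the two limits.
#'
#' @param y observed values, each in `[y_min, y_max]`.
#' @param mu latent means (recycled against `y`).
#' @param sigma latent SD, a single positive number.
#' @param y_min,y_max censoring limits (defaults 0 and 8 sessions/week).
#' @return numeric vector of log densities / log point masses.
#' @details At the limits the contribution is a normal tail probability
#'   (`log Phi((y_min-mu)/sigma)` at the floor, the upper-tail analogue at the
#'   ceiling), computed on the log scale so that means 30--40 SDs away from a
#'   limit remain finite.
#' @export
cnorm_log_density <- function(y, mu, sigma, y_min = 0, y_max = 8) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number")
  if (y_min >= y_max) stop("`y_min` must be below `y_max`")
  if (any(y < y_min | y > y_max, na.rm = TRUE))
    stop("observations outside the censoring limits")
  n <- max(length(y), length(mu))
  y <- rep_len(y, n)
  mu <- rep_len(mu, n)
  out <- numeric(n)
  lo <- y == y_min
  hi <- y == y_max
  mid <- !lo & !hi
  out[lo] <- stats::pnorm((y_min - mu[lo]) / sigma, log.p = TRUE)
  out[hi] <- stats::pnorm((y_max - mu[hi]) / sigma,
                          lower.tail = FALSE, log.p = TRUE)
  out[mid] <- stats::dnorm((y[mid] - mu[mid]) / sigma, log = TRUE) - log(sigma)
  out[is.na(y)] <- NA_real_
  out
}

#' Expected observed value under the censored-normal model
#'
#' Mean of the observed (clipped) outcome when the latent value is
#' `Normal(mu, sigma^2)` censored at `y_min` and `y_max`. Used to draw group
#' trajectory curves on the observed 0--8 sessions/week scale.
#'
#' With `a = (y_min - mu)/sigma` and `b = (y_max - mu)/sigma`:
#' `E = y_min Phi(a) + y_max (1 - Phi(b)) + mu (Phi(b) - Phi(a)) -
#'  sigma (phi(b) - phi(a))`. `sigma = 0` returns `mu` clipped to the limits.
#'
#' @inheritParams cnorm_log_density
#' @return numeric vector of expected observed values, always in
#'   `[y_min, y_max]`.
#' @export
cnorm_expected_observed <- function(mu, sigma, y_min = 0, y_max = 8) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative number")
  if (y_min >= y_max) stop("`y_min` must be below `y_max`")
  if (sigma == 0) return(pmin(pmax(mu, y_min), y_max))
  a <- (y_min - mu) / sigma
  b <- (y_max - mu) / sigma
  e <- y_min * stats::pnorm(a) +
    y_max * stats::pnorm(b, lower.tail = FALSE) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) -
    sigma * (stats::dnorm(b) - stats::dnorm(a))
  pmin(pmax(e, y_min), y_max)
}

# Score of the censored-normal log density, used by the EM M-step.
# Returns d(logf)/d(mu) and d(logf)/d(log sigma) for each observation.
cnorm_score <- function(y, mu, sigma, y_min = 0, y_max = 8) {
  n <- max(length(y), length(mu))
  y <- rep_len(y, n)
  mu <- rep_len(mu, n)
  dmu <- numeric(n)
  dls <- numeric(n)
  lo <- y == y_min
  hi <- y == y_max
  mid <- !lo & !hi
  if (any(mid)) {
    z <- (y[mid] - mu[mid]) / sigma
    dmu[mid] <- z / sigma
    dls[mid] <- z^2 - 1
  }
  if (any(lo)) {
    a <- (y_min - mu[lo]) / sigma
    # inverse Mills ratio phi(a)/Phi(a), stable in the deep left tail
    lam <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
    dmu[lo] <- -lam / sigma
    dls[lo] <- -a * lam
  }
  if (any(hi)) {
    b <- (y_max - mu[hi]) / sigma
    eta <- exp(stats::dnorm(b, log = TRUE) -
                 stats::pnorm(b, lower.tail = FALSE, log.p = TRUE))
    dmu[hi] <- eta / sigma
    dls[hi] <- b * eta
  }
  list(dmu = dmu, dlogsigma = dls)
}
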