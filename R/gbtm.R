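#' Trajectory model specification
#'
#' Defines the shape of a censored-normal group-based trajectory model:
#' number of latent groups, polynomial degree of the group mean curves, the
#' censoring limits of the outcome, and the affine age scaling used to build
#' the polynomial basis.
#'
#' Age is mapped to `[-1, 1]` over `age_range` before powers are taken, which
#' keeps the cubic design well conditioned; coefficients are always stored on
#' this scaled axis.
#'
#' @param G number of latent trajectory groups (>= 1).
#' @param order polynomial degree of the group mean curves (0--3; default 3,
#'   i.e. intercept + linear + quadratic + cubic age effects).
#' @param y_min,y_max censoring limits of the outcome (default 0 and 8
#'   sessions/week; 8 codes "more than seven").
#' @param age_range two ages (years) mapped to -1 and 1.
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(G, order = 3, y_min = 0, y_max = 8,
                            age_range = c(6, 16)) {
  G <- as.integer(G)
  order <- as.integer(order)
  stopifnot(G >= 1L, order >= 0L, order <= 3L, y_min < y_max,
            length(age_range) == 2L, age_range[1] < age_range[2])
  structure(
    list(G = G, order = order, y_min = y_min, y_max = y_max,
         age_range = as.numeric(age_range)),
    class = "trajectory_spec"
  )
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat(sprintf(
    "Censored-normal trajectory spec: %d group(s), polynomial order %d,\n",
    x$G, x$order))
  cat(sprintf("  outcome censored at [%g, %g], age %g-%g scaled to [-1, 1]\n",
              x$y_min, x$y_max, x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Map age in years onto the spec's scaled axis
#' @param spec a [trajectory_spec()].
#' @param age ages in years.
#' @return scaled ages (range `age_range` maps to `[-1, 1]`).
#' @export
scale_age <- function(spec, age) {
  c0 <- mean(spec$age_range)
  h <- diff(spec$age_range) / 2
  (age - c0) / h
}

# Polynomial design matrix on the scaled age axis: 1, a, a^2, ...
poly_basis <- function(spec, age) {
  a <- scale_age(spec, age)
  outer(a, 0:spec$order, `^`)
}

#' Parameters of a censored-normal trajectory model
#'
#' @param spec a [trajectory_spec()].
#' @param beta `G x (order+1)` matrix of polynomial coefficients on the
#'   scaled-age axis, one row per group.
#' @param sigma shared residual SD of the latent outcome (> 0).
#' @param theta `G - 1` membership log-odds relative to group 1 (omit or
#'   `numeric(0)` for `G = 1`). Membership probabilities `pi` are
#'   `softmax(c(0, theta))`.
#' @return an object of class `gbtm_params` with derived element `pi`.
#' @export
gbtm_params <- function(spec, beta, sigma, theta = numeric(0)) {
  stopifnot(inherits(spec, "trajectory_spec"))
  beta <- matrix(as.numeric(beta), nrow = spec$G)
  if (ncol(beta) != spec$order + 1L)
    stop("`beta` must have order+1 columns")
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be positive")
  theta <- as.numeric(theta)
  if (length(theta) != spec$G - 1L)
    stop("`theta` must have G-1 elements")
  if (any(!is.finite(theta))) stop("membership logits must be finite")
  lp <- c(0, theta)
  pi <- exp(lp - max(lp))
  pi <- pi / sum(pi)
  structure(list(spec = spec, beta = beta, sigma = sigma, theta = theta,
                 pi = pi),
            class = "gbtm_params")
}

# Validate and index a monthly panel for likelihood work. Keeps non-missing
# rows only; missing months contribute nothing under MCAR.
prepare_panel <- function(panel, spec) {
  need <- c("child_id", "age", "y")
  if (!all(need %in% names(panel)))
    stop("panel needs columns child_id, age, y")
  keep <- !is.na(panel$y)
  panel <- panel[keep, , drop = FALSE]
  if (nrow(panel) == 0L) stop("panel has no non-missing observations")
  if (any(panel$y < spec$y_min | panel$y > spec$y_max))
    stop("panel contains y outside the censoring limits")
  child <- factor(panel$child_id)   # sorted levels: row order never matters
  list(
    y = as.numeric(panel$y),
    X = poly_basis(spec, as.numeric(panel$age)),
    age = as.numeric(panel$age),
    child = child,
    child_ids = levels(child),
    idx = as.integer(child),
    n_obs = nrow(panel),
    n_children = nlevels(child)
  )
}

# n_obs x G matrix of per-observation censored-normal log densities.
obs_log_density <- function(pp, beta, sigma, spec) {
  mu <- pp$X %*% t(beta)                      # n_obs x G latent means
  out <- matrix(0, pp$n_obs, nrow(beta))
  for (j in seq_len(nrow(beta)))
    out[, j] <- cnorm_log_density(pp$y, mu[, j], sigma,
                                  spec$y_min, spec$y_max)
  out
}

#' Per-child conditional log-likelihood for each group
#'
#' Sums the censored-normal log density of a child's non-missing monthly
#' values under each group's polynomial mean curve (log L_ij). Months with
#' missing values are simply absent from the sum (MCAR).
#'
#' @param panel data frame with columns `child_id`, `age` (years), `y`.
#' @param params a [gbtm_params()].
#' @return matrix (children x groups) of log-likelihoods, with the child ids
#'   as row names (children ordered by first appearance in the panel).
#' @export
child_group_loglik <- function(panel, params) {
  spec <- params$spec
  pp <- prepare_panel(panel, spec)
  ld <- obs_log_density(pp, params$beta, params$sigma, spec)
  ll <- rowsum(ld, pp$idx, reorder = TRUE)
  rownames(ll) <- pp$child_ids
  ll
}

#' Mixture log-likelihood of a censored-normal trajectory model
#'
#' `l = sum_i log sum_j pi_j exp(log L_ij)`, evaluated with log-sum-exp.
#'
#' @inheritParams child_group_loglik
#' @return a single finite number.
#' @export
mixture_loglik <- function(panel, params) {
  ll <- child_group_loglik(panel, params)
  sum(log_row_sum_exp(sweep(ll, 2, log(params$pi), `+`)))
}

#' Posterior group-membership probabilities
#'
#' Bayes step `w_ij = pi_j L_ij / sum_l pi_l L_il` per child.
#'
#' @inheritParams child_group_loglik
#' @return matrix (children x groups) with rows summing to 1.
#' @export
posterior_probs <- function(panel, params) {
  ll <- child_group_loglik(panel, params)
  lw <- sweep(ll, 2, log(params$pi), `+`)
  w <- exp(lw - log_row_sum_exp(lw))
  w / rowSums(w)
}

log_row_sum_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Number of free parameters of a trajectory model
#'
#' `G (order+1)` polynomial coefficients, `G - 1` membership logits, and one
#' shared residual SD: `k = G (order + 1) + (G - 1) + 1`. For cubic curves
#' this is `5 G`.
#'
#' @param spec a [trajectory_spec()].
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  as.integer(spec$G * (spec$order + 1L) + (spec$G - 1L) + 1L)
}

#' Fit a censored-normal group-based trajectory model
#'
#' Maximum-likelihood fit by EM with multiple seeded starts. The E-step
#' computes posterior membership probabilities; the M-step maximises the
#' posterior-weighted censored-normal regression over all group coefficient
#' vectors and the shared log-SD by BFGS (warm-started, so the observed-data
#' log-likelihood never decreases); membership probabilities have a closed
#' form. The first start partitions children by k-means on their mean
#' outcome; remaining starts perturb a pooled fit at random. Groups in the
#' returned fit are relabelled in increasing order of mean fitted trajectory,
#' so group 1 is always the least active.
#'
#' @param panel data frame with columns `child_id`, `age` (years), `y`
#'   (monthly average weekly sessions, `NA` allowed).
#' @param G number of latent groups; ignored when `spec` is given.
#' @param spec optional [trajectory_spec()]; by default a cubic spec whose
#'   age range is the observed range of `panel$age`.
#' @param n_starts number of EM starts.
#' @param seed integer seed controlling starts (recorded in the fit).
#' @param tol convergence tolerance: stop when the log-likelihood improves by
#'   less than `tol` on 3 consecutive iterations.
#' @param max_iter maximum EM iterations per start.
#' @param order polynomial degree when `spec` is not supplied.
#' @return an object of class `gbtm_fit`: the spec, a [gbtm_params()], the
#'   log-likelihood, posterior matrix `w`, modal `assignment` (ties to the
#'   lowest group index), the log-likelihood trace of the winning start, and
#'   bookkeeping (`n_obs`, `n_children`, `seed`, `converged`).
#' @export
fit_gbtm <- function(panel, G, spec = NULL, n_starts = 3, seed = 1,
                     tol = 1e-6, max_iter = 500, order = 3) {
  if (is.null(spec)) {
    keep <- !is.na(panel$y)
    rng <- range(panel$age[keep])
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    spec <- trajectory_spec(G, order = order, age_range = rng)
  }
  G <- spec$G
  pp <- prepare_panel(panel, spec)
  set.seed(as.integer(seed))
  starts <- make_starts(pp, spec, n_starts)

  best <- NULL
  for (s in seq_along(starts)) {
    fit <- tryCatch(
      em_run(pp, spec, starts[[s]], tol = tol, max_iter = max_iter),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
      best$start_used <- s
    }
  }
  if (is.null(best)) stop("all EM starts failed")
  if (!best$converged)
    warning("EM did not reach the convergence tolerance; returning best fit")

  out <- relabel_fit(best, pp, spec)
  out$seed <- as.integer(seed)
  out$n_obs <- pp$n_obs
  out$n_children <- pp$n_children
  out$child_ids <- pp$child_ids
  out$panel_age_range <- range(pp$age)
  out$data <- pp
  class(out) <- "gbtm_fit"
  out
}

#' @export
print.gbtm_fit <- function(x, ...) {
  spec <- x$params$spec
  cat(sprintf("Censored-normal GBTM fit: G = %d, order %d\n",
              spec$G, spec$order))
  cat(sprintf("  log-likelihood %.3f on %d observations / %d children\n",
              x$loglik, x$n_obs, x$n_children))
  cat("  group shares (pi): ",
      paste(sprintf("%.3f", x$params$pi), collapse = "  "), "\n", sep = "")
  cat("  modal group sizes: ",
      paste(tabulate(x$assignment, spec$G), collapse = "  "), "\n", sep = "")
  invisible(x)
}

# ---- internals ----------------------------------------------------------

make_starts <- function(pp, spec, n_starts) {
  G <- spec$G
  p <- spec$order + 1L
  ybar <- tapply(pp$y, pp$idx, mean)
  pooled <- pooled_lm_start(pp, spec)
  starts <- vector("list", n_starts)

  # start 1: k-means partition of child-level mean y
  grp <- if (G == 1L) rep(1L, pp$n_children) else {
    centers <- stats::quantile(ybar, probs = (seq_len(G) - 0.5) / G,
                               names = FALSE)
    centers <- centers + stats::rnorm(G, 0, 1e-4)  # distinct centers
    km <- tryCatch(stats::kmeans(ybar, centers = matrix(sort(centers))),
                   error = function(e) NULL)
    if (is.null(km)) cut(rank(ybar, ties.method = "first"), G, labels = FALSE)
    else match(km$cluster, order(km$centers))  # clusters relabelled by center
  }
  starts[[1]] <- partition_start(pp, spec, grp, pooled)

  for (s in seq_len(n_starts)[-1]) {
    beta <- matrix(rep(pooled$beta, each = G), nrow = G) +
      matrix(stats::rnorm(G * p, 0, c(1.5, 0.8, 0.5, 0.5)[seq_len(p)][col(matrix(0, G, p))]),
             nrow = G)
    pi0 <- stats::runif(G, 0.2, 1)
    pi0 <- pi0 / sum(pi0)
    starts[[s]] <- list(beta = beta, sigma = pooled$sigma * stats::runif(1, 0.8, 1.5),
                        pi = pi0)
  }
  starts
}

# Ordinary polynomial regression of y on scaled age, ignoring censoring;
# a serviceable centre for random starts.
pooled_lm_start <- function(pp, spec) {
  fit <- stats::lm.fit(pp$X, pp$y)
  sig <- sqrt(mean(fit$residuals^2))
  list(beta = unname(fit$coefficients), sigma = max(sig, 0.2))
}

partition_start <- function(pp, spec, grp, pooled) {
  G <- spec$G
  p <- spec$order + 1L
  beta <- matrix(rep(pooled$beta, each = G), nrow = G)
  for (j in seq_len(G)) {
    rows <- pp$idx %in% which(grp == j)
    if (sum(rows) > p + 2L) {
      bj <- tryCatch(stats::lm.fit(pp$X[rows, , drop = FALSE], pp$y[rows]),
                     error = function(e) NULL)
      if (!is.null(bj) && all(is.finite(bj$coefficients)))
        beta[j, ] <- bj$coefficients
    } else {
      beta[j, 1] <- beta[j, 1] + stats::rnorm(1, 0, 0.5)
    }
  }
  shares <- tabulate(grp, G) / length(grp)
  shares <- pmax(shares, 0.02)
  list(beta = beta, sigma = pooled$sigma, pi = shares / sum(shares))
}

em_run <- function(pp, spec, start, tol, max_iter) {
  G <- spec$G
  p <- spec$order + 1L
  beta <- start$beta
  sigma <- start$sigma
  pi <- start$pi
  ll_old <- -Inf
  trace <- numeric(0)
  below <- 0L
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    ld <- obs_log_density(pp, beta, sigma, spec)
    llmat <- rowsum(ld, pp$idx, reorder = TRUE)
    lw <- sweep(llmat, 2, log(pi), `+`)
    lse <- log_row_sum_exp(lw)
    ll <- sum(lse)
    if (!is.finite(ll)) stop("non-finite log-likelihood")
    trace <- c(trace, ll)
    if (ll < ll_old - 1e-8 * (abs(ll_old) + 1))
      stop("log-likelihood decreased during EM")
    if (abs(ll - ll_old) < tol) below <- below + 1L else below <- 0L
    if (below >= 3L) { converged <- TRUE; break }
    ll_old <- ll

    w <- exp(lw - lse)                      # E-step: children x G
    w <- w / rowSums(w)
    pi <- pmax(colMeans(w), 1e-8)
    pi <- pi / sum(pi)

    # M-step: posterior-weighted censored-normal regression, shared sigma
    wobs <- w[pp$idx, , drop = FALSE]       # n_obs x G weights
    par0 <- c(as.vector(beta), log(sigma))
    qfun <- function(par) {
      if (!all(is.finite(par)) || abs(par[G * p + 1L]) > 20) return(1e300)
      b <- matrix(par[seq_len(G * p)], nrow = G)
      s <- exp(par[G * p + 1L])
      val <- -sum(wobs * obs_log_density(pp, b, s, spec))
      if (!is.finite(val)) 1e300 else val
    }
    qgrad <- function(par) {
      if (!all(is.finite(par)) || abs(par[G * p + 1L]) > 20)
        return(numeric(G * p + 1L))
      b <- matrix(par[seq_len(G * p)], nrow = G)
      s <- exp(par[G * p + 1L])
      mu <- pp$X %*% t(b)
      gb <- matrix(0, G, p)
      gs <- 0
      for (j in seq_len(G)) {
        sc <- cnorm_score(pp$y, mu[, j], s, spec$y_min, spec$y_max)
        gb[j, ] <- crossprod(pp$X, wobs[, j] * sc$dmu)
        gs <- gs + sum(wobs[, j] * sc$dlogsigma)
      }
      -c(as.vector(gb), gs)
    }
    # generalized EM: a few BFGS steps from the warm start are enough to
    # improve Q; the fixed point is unchanged and iterations stay cheap
    opt <- stats::optim(par0, qfun, qgrad, method = "BFGS",
                        control = list(maxit = 15, reltol = 1e-9))
    beta <- matrix(opt$par[seq_len(G * p)], nrow = G)
    sigma <- exp(opt$par[G * p + 1L])
  }

  ld <- obs_log_density(pp, beta, sigma, spec)
  llmat <- rowsum(ld, pp$idx, reorder = TRUE)
  lw <- sweep(llmat, 2, log(pi), `+`)
  lse <- log_row_sum_exp(lw)
  w <- exp(lw - lse)
  w <- w / rowSums(w)
  list(beta = beta, sigma = sigma, pi = pi, w = w,
       loglik = sum(lse), ll_trace = trace, n_iter = length(trace),
       converged = converged)
}

relabel_fit <- function(fit, pp, spec) {
  G <- spec$G
  grid <- seq(min(pp$age), max(pp$age), length.out = 25)
  Xg <- poly_basis(spec, grid)
  curves <- Xg %*% t(fit$beta)
  means <- colMeans(apply(curves, 2, cnorm_expected_observed,
                          sigma = fit$sigma, y_min = spec$y_min,
                          y_max = spec$y_max))
  ord <- order(means)
  beta <- fit$beta[ord, , drop = FALSE]
  pi <- fit$pi[ord]
  w <- fit$w[, ord, drop = FALSE]
  theta <- if (G > 1L) log(pi[-1] / pi[1]) else numeric(0)
  params <- gbtm_params(spec, beta, fit$sigma, theta)
  assignment <- max.col(w, ties.method = "first")
  list(params = params, loglik = fit$loglik, w = w,
       assignment = assignment, ll_trace = fit$ll_trace,
       n_iter = fit$n_iter, converged = fit$converged,
       start_used = fit$start_used)
}
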