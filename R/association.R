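#' Multinomial logistic regression of trajectory group membership
#'
#' Maximum-likelihood multinomial logit with the first outcome level (the
#' least active trajectory group) as reference, fitted by [nnet::multinom()]
#' with a tight convergence tolerance. Exponentiated coefficients are
#' relative risk ratios (RRR): the ratio of membership odds versus the
#' reference group per unit of the covariate.
#'
#' @param outcome factor of group labels per child (first level =
#'   reference).
#' @param design data frame of covariates (factors are indicator-coded
#'   against their first level).
#' @param weights optional case weights (e.g. cell counts).
#' @return object of class `assoc_fit`: the coefficient matrix (rows =
#'   non-reference outcome levels), log-likelihood, fitted probabilities,
#'   model matrix, and the packed coefficient ordering used by
#'   [cluster_robust_vcov()].
#' @export
fit_multinomial <- function(outcome, design, weights = NULL) {
  outcome <- droplevels(as.factor(outcome))
  if (nlevels(outcome) < 2) stop("need at least 2 outcome categories")
  intercept_only <- is.null(design) || ncol(as.data.frame(design)) == 0L
  if (intercept_only) {
    df <- data.frame(.y = outcome)
    X <- matrix(1, length(outcome), 1,
                dimnames = list(NULL, "(Intercept)"))
    fml <- .y ~ 1
  } else {
    df <- data.frame(.y = outcome, design, check.names = TRUE)
    X <- stats::model.matrix(~ ., data = df[-1])
    fml <- .y ~ .
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  w <- if (is.null(weights)) rep(1, nrow(df)) else as.numeric(weights)
  fit <- nnet::multinom(fml, data = df, weights = w, trace = FALSE,
                        maxit = 1000, reltol = 1e-14)
  cf <- stats::coef(fit)
  if (nlevels(outcome) == 2) cf <- matrix(cf, nrow = 1,
                                          dimnames = list(levels(outcome)[2],
                                                          names(cf)))
  if (any(abs(cf) > 20))
    stop("apparent separation: coefficient diverging for ",
         paste(colnames(cf)[apply(abs(cf) > 20, 2, any)], collapse = ", "))
  probs <- stats::fitted(fit)
  if (is.null(dim(probs)) || ncol(probs) == 1L)   # 2-level: P(level 2) only
    probs <- cbind(1 - as.vector(probs), as.vector(probs))
  colnames(probs) <- levels(outcome)
  structure(list(
    coef = cf, loglik = -fit$deviance / 2, deviance = fit$deviance,
    probs = probs, X = X, y = outcome, weights = w,
    levels = levels(outcome), terms = colnames(X), nnet_fit = fit
  ), class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("Multinomial logit: %d outcome levels (ref '%s'), %d terms\n",
              length(x$levels), x$levels[1], length(x$terms)))
  cat(sprintf("  log-likelihood %.3f on %d rows\n", x$loglik, nrow(x$X)))
  print(round(exp(x$coef), 3))
  invisible(x)
}

# Packed score matrix: one row per data row, columns ordered outcome-major
# (all terms for outcome level 2, then level 3, ...). For the multinomial
# logit the score for level j is (1{y=j} - p_j) * x.
multinom_scores <- function(fit) {
  lev <- fit$levels
  X <- fit$X
  p <- ncol(X)
  J <- length(lev)
  out <- matrix(0, nrow(X), p * (J - 1))
  for (j in 2:J) {
    r <- (fit$y == lev[j]) - fit$probs[, j]
    out[, (j - 2) * p + seq_len(p)] <- fit$weights * r * X
  }
  colnames(out) <- as.vector(t(outer(lev[-1], colnames(X), paste,
                                     sep = ":")))
  out
}

# Observed (= expected, canonical link) information of the multinomial
# logit, same packing as multinom_scores.
multinom_information <- function(fit) {
  X <- fit$X
  p <- ncol(X)
  J <- length(fit$levels)
  A <- matrix(0, p * (J - 1), p * (J - 1))
  for (j in 2:J) {
    for (k in 2:J) {
      wjk <- fit$probs[, j] * ((j == k) - fit$probs[, k])
      blk <- crossprod(X, fit$weights * wjk * X)
      A[(j - 2) * p + seq_len(p), (k - 2) * p + seq_len(p)] <- blk
    }
  }
  A
}

#' Cluster-robust covariance for a multinomial fit
#'
#' Sandwich estimator `A^-1 (M/(M-1) sum_c s_c s_c') A^-1` where `s_c` sums
#' the per-row score contributions within cluster `c` and `A` is the
#' observed information; allows arbitrary within-cluster correlation (e.g.
#' children in the same school). With every row its own cluster this is the
#' usual heteroskedasticity-robust sandwich up to the small-sample factor.
#'
#' @param fit an [fit_multinomial()] result.
#' @param cluster_ids cluster label per data row (>= 2 distinct clusters).
#' @return symmetric covariance matrix in the packed (outcome-major)
#'   coefficient ordering.
#' @export
cluster_robust_vcov <- function(fit, cluster_ids) {
  stopifnot(length(cluster_ids) == nrow(fit$X))
  cl <- factor(cluster_ids)
  M <- nlevels(cl)
  if (M < 2) stop("need at least 2 clusters")
  S <- multinom_scores(fit)
  Sc <- rowsum(S, cl)
  meat <- crossprod(Sc) * M / (M - 1)
  A <- multinom_information(fit)
  Ainv <- solve(A)
  V <- Ainv %*% meat %*% Ainv
  (V + t(V)) / 2
}

#' Model-based covariance of a multinomial fit
#'
#' Inverse observed information, for comparison with the cluster-robust
#' sandwich.
#' @param fit an [fit_multinomial()] result.
#' @return covariance matrix in the packed coefficient ordering.
#' @export
model_vcov <- function(fit) solve(multinom_information(fit))

#' Relative-risk-ratio table
#'
#' Formats a multinomial fit as an RRR table: point estimate `exp(b)`, the
#' Wald confidence interval `exp(b +/- z se)` from the supplied covariance,
#' and significance stars at 0.05 / 0.01.
#'
#' @param fit an [fit_multinomial()] result.
#' @param vcov covariance in the packed ordering (e.g.
#'   [cluster_robust_vcov()]); defaults to the model-based one.
#' @param level confidence level (default 0.95).
#' @return tibble: `group`, `term`, `b`, `se`, `rrr`, `ci_lo`, `ci_hi`,
#'   `p`, `stars`.
#' @export
rrr_table <- function(fit, vcov = NULL, level = 0.95) {
  if (is.null(vcov)) vcov <- model_vcov(fit)
  lev <- fit$levels
  p <- length(fit$terms)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se_all <- sqrt(pmax(diag(vcov), 0))
  rows <- list()
  for (j in 2:length(lev)) {
    b <- fit$coef[j - 1, ]
    se <- se_all[(j - 2) * p + seq_len(p)]
    pv <- 2 * stats::pnorm(-abs(b / se))
    rows[[j - 1]] <- tibble::tibble(
      group = lev[j], term = fit$terms, b = unname(b), se = se,
      rrr = exp(unname(b)),
      ci_lo = exp(unname(b) - z * se), ci_hi = exp(unname(b) + z * se),
      p = pv,
      stars = ifelse(pv < 0.01, "**", ifelse(pv < 0.05, "*", ""))
    )
  }
  dplyr::bind_rows(rows)
}

#' Likelihood-ratio test of nested multinomial fits
#'
#' Chi-square test of the full model against a null fitted on the same
#' data, with degrees of freedom equal to the difference in parameter
#' counts.
#'
#' @param fit,null_fit nested [fit_multinomial()] results (same rows, same
#'   outcome).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
overall_test <- function(fit, null_fit) {
  if (nrow(fit$X) != nrow(null_fit$X) ||
        !identical(fit$levels, null_fit$levels))
    stop("models are not nested on the same data")
  df <- (length(fit$terms) - length(null_fit$terms)) *
    (length(fit$levels) - 1)
  if (df < 0) stop("`fit` must be the larger model")
  stat <- max(0, 2 * (fit$loglik - null_fit$loglik))
  list(statistic = stat, df = df,
       p_value = if (df == 0) 1 else stats::pchisq(stat, df,
                                                   lower.tail = FALSE))
}
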