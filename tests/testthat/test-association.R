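# Tertile-by-group counts of the total motor-performance score from a
# reference cohort's descriptive table (groups 1..5 in columns low/middle/
# high order). With a single categorical predictor the multinomial MLE is
# saturated, so every fitted RRR must equal a cross-ratio of these counts.
tertile_counts <- function() {
  tab <- rbind(
    g1 = c(67, 50, 28),
    g2 = c(108, 99, 77),
    g3 = c(106, 103, 105),
    g4 = c(72, 83, 108),
    g5 = c(18, 35, 50)
  )
  colnames(tab) <- c("low", "middle", "high")
  tab
}

test_that("an intercept-only multinomial recovers the observed shares", {
  y <- factor(rep(c("a", "b", "c"), times = c(20, 30, 50)))
  fit <- fit_multinomial(y, data.frame(row.names = seq_along(y)))
  expect_equal(unname(fit$probs[1, ]), c(0.2, 0.3, 0.5), tolerance = 1e-6)
})

test_that("univariable RRRs equal the contingency-table cross-ratios", {
  tab <- tertile_counts()
  d <- expand_counts(tab)
  fit <- fit_multinomial(factor(d$group),
                         data.frame(tertile = factor(d$tertile,
                                                     c("low", "middle",
                                                       "high"))))
  rrr <- rrr_table(fit)
  # group 5 vs 1, high vs low: (50/18)/(28/67)
  r5h <- rrr$rrr[rrr$group == "g5" & rrr$term == "tertilehigh"]
  expect_equal(r5h, (50 / 18) / (28 / 67), tolerance = 1e-4)
  expect_equal(r5h, 6.647, tolerance = 1e-3)
  # every cell: fitted RRR = cross-ratio of counts
  for (g in rownames(tab)[-1]) for (tt in c("middle", "high")) {
    expected <- (tab[g, tt] / tab["g1", tt]) / (tab[g, "low"] / tab["g1", "low"])
    got <- rrr$rrr[rrr$group == g & rrr$term == paste0("tertile", tt)]
    expect_equal(got, expected, tolerance = 1e-4)
  }
})

test_that("weighted count fits match expanded individual-level fits", {
  tab <- tertile_counts()[c("g1", "g5"), ]
  d <- expand_counts(tab)
  cells <- as.data.frame(as.table(tab))
  names(cells) <- c("group", "tertile", "n")
  f1 <- fit_multinomial(factor(d$group),
                        data.frame(tertile = factor(d$tertile,
                                                    colnames(tab))))
  f2 <- fit_multinomial(factor(cells$group),
                        data.frame(tertile = factor(cells$tertile,
                                                    colnames(tab))),
                        weights = cells$n)
  expect_equal(unname(f1$coef), unname(f2$coef), tolerance = 1e-6)
})

test_that("reference recoding is invertible on the RRR scale", {
  tab <- tertile_counts()
  d <- expand_counts(tab)
  tert <- factor(d$tertile, c("low", "middle", "high"))
  f_low <- fit_multinomial(factor(d$group), data.frame(tertile = tert))
  f_high <- fit_multinomial(factor(d$group),
                            data.frame(tertile = stats::relevel(tert,
                                                                "high")))
  r_low <- rrr_table(f_low)
  r_high <- rrr_table(f_high)
  # RRR(high vs low) = 1 / RRR(low vs high), per group
  for (g in paste0("g", 2:5)) {
    a <- r_low$rrr[r_low$group == g & r_low$term == "tertilehigh"]
    b <- r_high$rrr[r_high$group == g & r_high$term == "tertilelow"]
    expect_equal(a, 1 / b, tolerance = 1e-4)
  }
})

test_that("perfect separation and rank deficiency are detected", {
  y <- factor(rep(c("a", "b"), each = 20))
  x <- rep(c(0, 1), each = 20)
  expect_error(fit_multinomial(y, data.frame(x = x)), "separation")
  expect_error(
    fit_multinomial(factor(rep(c("a", "b"), 10)),
                    data.frame(x = 1:20, x2 = 2 * (1:20))),
    "rank deficient")
})

test_that("cluster-robust sandwich matches brute-force assembly", {
  set.seed(30)
  n <- 30
  x <- rnorm(n)
  cl <- rep(1:6, each = 5)
  y <- factor(sample(c("a", "b", "c"), n, replace = TRUE,
                     prob = c(0.4, 0.3, 0.3)))
  fit <- fit_multinomial(y, data.frame(x = x))
  V <- cluster_robust_vcov(fit, cl)
  expect_equal(V, t(V), tolerance = 1e-12)
  expect_true(all(eigen(V, only.values = TRUE)$values > -1e-10))

  # independent brute-force computation of scores, bread and meat
  X <- cbind(1, x)
  P <- fit$probs
  lev <- levels(y)
  S <- matrix(0, n, 4)
  for (i in 1:n) for (j in 2:3)
    S[i, (j - 2) * 2 + 1:2] <- ((y[i] == lev[j]) - P[i, j]) * X[i, ]
  A <- matrix(0, 4, 4)
  for (i in 1:n) for (j in 2:3) for (k in 2:3)
    A[(j - 2) * 2 + 1:2, (k - 2) * 2 + 1:2] <-
      A[(j - 2) * 2 + 1:2, (k - 2) * 2 + 1:2] +
      P[i, j] * ((j == k) - P[i, k]) * X[i, ] %o% X[i, ]
  Sc <- rowsum(S, cl)
  Vb <- solve(A) %*% (crossprod(Sc) * 6 / 5) %*% solve(A)
  expect_equal(V, (Vb + t(Vb)) / 2, tolerance = 1e-8)

  expect_error(cluster_robust_vcov(fit, rep(1, n)), "2 clusters")
})

test_that("duplicating every cluster halves the robust variance", {
  set.seed(8)
  n <- 40
  x <- rnorm(n)
  cl <- rep(1:8, each = 5)
  y <- factor(ifelse(runif(n) < plogis(x), "hi", "lo"))
  fit <- fit_multinomial(y, data.frame(x = x))
  V1 <- cluster_robust_vcov(fit, cl)
  fit2 <- fit_multinomial(factor(c(as.character(y), as.character(y))),
                          data.frame(x = c(x, x)))
  V2 <- cluster_robust_vcov(fit2, c(cl, cl + 100))
  # doubling bread and meat: variance halves (up to the M/(M-1) factors)
  ratio <- diag(V1) / diag(V2)
  adj <- (8 / 7) / (16 / 15)
  expect_equal(unname(ratio), rep(2 * adj, 2), tolerance = 1e-6)
})

test_that("singleton clusters reduce to the heteroskedastic sandwich", {
  set.seed(9)
  n <- 60
  x <- rnorm(n)
  y <- factor(ifelse(runif(n) < plogis(0.5 * x), "hi", "lo"))
  fit <- fit_multinomial(y, data.frame(x = x))
  V <- cluster_robust_vcov(fit, seq_len(n))
  S <- sporttraj:::multinom_scores(fit)
  A <- sporttraj:::multinom_information(fit)
  Vhc <- solve(A) %*% (crossprod(S) * n / (n - 1)) %*% solve(A)
  expect_equal(V, (Vhc + t(Vhc)) / 2, tolerance = 1e-10)
})

test_that("RRR tables exponentiate Wald intervals", {
  tab <- rrr_table(list(levels = c("r", "g"),
                        coef = matrix(c(0.5), 1, 1,
                                      dimnames = list("g", "x")),
                        terms = "x"),
                   vcov = matrix(0.2^2, 1, 1))
  expect_equal(tab$rrr, exp(0.5), tolerance = 1e-12)
  expect_equal(tab$ci_lo, exp(0.5 - qnorm(0.975) * 0.2), tolerance = 1e-12)
  expect_equal(tab$ci_hi, exp(0.5 + qnorm(0.975) * 0.2), tolerance = 1e-12)
  expect_equal(round(c(tab$rrr, tab$ci_lo, tab$ci_hi), 3),
               c(1.649, 1.114, 2.440))
  # b = 0: RRR 1 with a CI centred at 1 on the log scale
  tab0 <- rrr_table(list(levels = c("r", "g"),
                         coef = matrix(0, 1, 1,
                                       dimnames = list("g", "x")),
                         terms = "x"),
                    vcov = matrix(0.3^2, 1, 1))
  expect_equal(tab0$rrr, 1)
  expect_equal(tab0$ci_lo * tab0$ci_hi, 1, tolerance = 1e-12)
})

test_that("the overall likelihood-ratio test behaves", {
  tab <- tertile_counts()
  d <- expand_counts(tab)
  y <- factor(d$group)
  tert <- data.frame(tertile = factor(d$tertile, colnames(tertile_counts())))
  full <- fit_multinomial(y, tert)
  null <- fit_multinomial(y, data.frame(row.names = seq_along(y)))
  lr <- overall_test(full, null)
  expect_equal(lr$df, 8)
  expect_gt(lr$statistic, 0)
  expect_equal(lr$p_value,
               pchisq(lr$statistic, 8, lower.tail = FALSE))
  # identical models: p = 1
  same <- overall_test(full, full)
  expect_equal(same$p_value, 1)
  # frozen chi-square tail: LR 20 on 8 df
  expect_equal(pchisq(20, 8, lower.tail = FALSE), 0.010336, tolerance = 1e-4)
  expect_error(overall_test(null, full), "larger")
})
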