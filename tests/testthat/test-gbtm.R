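test_that("parameter counts follow the cubic shared-sigma bookkeeping", {
  expect_equal(count_parameters(trajectory_spec(1)), 5L)
  expect_equal(count_parameters(trajectory_spec(5)), 25L)
  expect_equal(count_parameters(trajectory_spec(2, order = 0)), 4L)
  for (G in 1:10)
    expect_equal(count_parameters(trajectory_spec(G)), 5L * G)
})

test_that("child-group log-likelihood sums censored densities over months", {
  spec <- trajectory_spec(1, order = 0, age_range = c(6, 16))
  p <- gbtm_params(spec, beta = 3, sigma = 1)
  one <- tibble::tibble(child_id = "a", age = 10, y = 3)
  expect_equal(unname(child_group_loglik(one, p)[1, 1]),
               cnorm_log_density(3, 3, 1))
  # missing months contribute nothing
  two <- tibble::tibble(child_id = "a", age = c(10, 11, 12),
                        y = c(3, NA, 5))
  expect_equal(unname(child_group_loglik(two, p)[1, 1]),
               cnorm_log_density(3, 3, 1) + cnorm_log_density(5, 3, 1))
  # an all-missing panel is an upstream bug
  expect_error(child_group_loglik(
    tibble::tibble(child_id = "a", age = 10, y = NA_real_), p),
    "non-missing")
})

test_that("mixture log-likelihood matches brute-force summation", {
  spec <- trajectory_spec(2, order = 1, age_range = c(6, 16))
  p <- gbtm_params(spec, beta = rbind(c(1, 0.5), c(5, -1)), sigma = 1.2,
                   theta = log(0.6 / 0.4))
  panel <- toy_panel()
  # brute force: per child, pi-weighted product of censored densities
  ll_brute <- 0
  for (id in unique(panel$child_id)) {
    rows <- panel[panel$child_id == id, ]
    a <- scale_age(spec, rows$age)
    li <- 0
    for (j in 1:2) {
      mu <- p$beta[j, 1] + p$beta[j, 2] * a
      li <- li + p$pi[j] * prod(exp(cnorm_log_density(rows$y, mu, 1.2)))
    }
    ll_brute <- ll_brute + log(li)
  }
  expect_equal(mixture_loglik(panel, p), ll_brute, tolerance = 1e-12)
})

test_that("the mixture collapses under one group or identical groups", {
  spec1 <- trajectory_spec(1, order = 1, age_range = c(6, 16))
  p1 <- gbtm_params(spec1, beta = c(3, 1), sigma = 1)
  panel <- toy_panel()
  expect_equal(mixture_loglik(panel, p1),
               sum(child_group_loglik(panel, p1)))
  # two identical groups at pi = (1/2, 1/2) give the same likelihood
  spec2 <- trajectory_spec(2, order = 1, age_range = c(6, 16))
  p2 <- gbtm_params(spec2, beta = rbind(c(3, 1), c(3, 1)), sigma = 1,
                    theta = 0)
  expect_equal(mixture_loglik(panel, p2), mixture_loglik(panel, p1),
               tolerance = 1e-12)
})

test_that("label permutation leaves the mixture likelihood unchanged", {
  spec <- trajectory_spec(3, order = 1, age_range = c(6, 16))
  p <- gbtm_params(spec, beta = rbind(c(1, 0), c(3, 1), c(6, -1)),
                   sigma = 1, theta = c(0.4, -0.2))
  perm <- c(3, 1, 2)
  pi_p <- p$pi[perm]
  pp <- gbtm_params(spec, beta = p$beta[perm, ], sigma = 1,
                    theta = log(pi_p[-1] / pi_p[1]))
  panel <- toy_panel()
  expect_equal(mixture_loglik(panel, p), mixture_loglik(panel, pp),
               tolerance = 1e-10)
})

test_that("posteriors follow Bayes' rule", {
  spec <- trajectory_spec(2, order = 0, age_range = c(6, 16))
  panel <- toy_panel()
  # identical groups: posterior equals the prior
  p_eq <- gbtm_params(spec, beta = c(3, 3), sigma = 1,
                      theta = log(0.7 / 0.3))
  w <- posterior_probs(panel, p_eq)
  expect_equal(unname(w),
               matrix(rep(c(0.3, 0.7), each = 2), 2), tolerance = 1e-12)
  # dominance: one group overwhelmingly more likely
  p_dom <- gbtm_params(spec, beta = c(2.5, 8), sigma = 0.3, theta = 0)
  wd <- posterior_probs(tibble::tibble(child_id = "a", age = 10, y = 2.5),
                        p_dom)
  expect_gt(wd[1, 1], 1 - 1e-10)
  # hand Bayes on a single observation
  p2 <- gbtm_params(spec, beta = c(2, 4), sigma = 1, theta = log(0.4 / 0.6))
  one <- tibble::tibble(child_id = "a", age = 10, y = 3)
  l1 <- exp(cnorm_log_density(3, 2, 1))
  l2 <- exp(cnorm_log_density(3, 4, 1))
  expect_equal(posterior_probs(one, p2)[1, ],
               c(0.6 * l1, 0.4 * l2) / (0.6 * l1 + 0.4 * l2),
               tolerance = 1e-12)
  # rows always sum to 1
  p3 <- gbtm_params(spec, beta = c(2, 5), sigma = 1, theta = 0.3)
  expect_equal(unname(rowSums(posterior_probs(panel, p3))), c(1, 1),
               tolerance = 1e-10)
})

test_that("with no censored data a one-group fit is the least-squares fit", {
  set.seed(3)
  ages <- seq(7, 15, length.out = 20)
  ids <- sprintf("c%02d", 1:30)
  panel <- tidyr::expand_grid(child_id = ids, age = ages)
  spec <- trajectory_spec(1, order = 2, age_range = c(6, 16))
  a <- scale_age(spec, panel$age)
  panel$y <- 4 + 0.8 * a - 0.5 * a^2 + rnorm(nrow(panel), 0, 0.3)
  stopifnot(all(panel$y > 0 & panel$y < 8))
  fit <- fit_gbtm(panel, spec = spec, n_starts = 1, seed = 1)
  X <- cbind(1, a, a^2)
  ls <- lm.fit(X, panel$y)
  expect_equal(unname(fit$params$beta[1, ]), unname(ls$coefficients),
               tolerance = 1e-6)
  expect_equal(fit$params$sigma, sqrt(mean(ls$residuals^2)),
               tolerance = 1e-6)
})

test_that("EM is monotone, deterministic, and beats the generating truth", {
  true <- separated_params_3g()
  gen <- generate_model_faithful_panel(true, seq(6, 16, length.out = 12),
                                       n_children = 90, seed = 21)
  fit <- fit_gbtm(gen$panel, spec = true$spec, n_starts = 2, seed = 5)
  expect_true(all(diff(fit$ll_trace) > -1e-6 * (abs(fit$loglik) + 1)))
  expect_gte(fit$loglik, mixture_loglik(gen$panel, true))
  expect_equal(unname(rowSums(fit$w)), rep(1, fit$n_children),
               tolerance = 1e-10)
  expect_true(all(fit$params$pi > 0))
  expect_equal(sum(fit$params$pi), 1, tolerance = 1e-12)
  # modal assignment is the argmax with ties to the lowest index
  expect_equal(fit$assignment, max.col(fit$w, ties.method = "first"))
  # groups are ordered least to most active
  grid <- seq(6, 16, length.out = 20)
  curves <- sapply(1:3, function(j) mean(cnorm_expected_observed(
    sporttraj:::poly_basis(true$spec, grid) %*% fit$params$beta[j, ],
    fit$params$sigma)))
  expect_true(all(diff(curves) > 0))
  # seeded determinism
  fit2 <- fit_gbtm(gen$panel, spec = true$spec, n_starts = 2, seed = 5)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 0)
  expect_identical(fit$assignment, fit2$assignment)
})

test_that("the optimizer matches a dense grid search on a tiny instance", {
  spec <- trajectory_spec(2, order = 0, age_range = c(6, 16))
  panel <- tibble::tibble(
    child_id = rep(c("a", "b", "c"), each = 2),
    age = rep(c(9, 12), 3),
    y = c(1.0, 1.4, 5.2, 5.0, 1.2, 0.9)
  )
  fit <- fit_gbtm(panel, spec = spec, n_starts = 4, seed = 2)
  grid_ll <- -Inf
  for (b1 in seq(0, 3, by = 0.1)) for (b2 in seq(3.5, 6.5, by = 0.1))
    for (s in seq(0.1, 0.8, by = 0.1)) for (pi1 in c(0.2, 1 / 3, 0.5, 0.8)) {
      p <- gbtm_params(spec, beta = c(b1, b2), sigma = s,
                       theta = log((1 - pi1) / pi1))
      grid_ll <- max(grid_ll, mixture_loglik(panel, p))
    }
  expect_gte(fit$loglik, grid_ll - 1e-6)
})

test_that("trajectory predictions match the observation model", {
  true <- separated_params_3g()
  gen <- generate_model_faithful_panel(true, seq(6, 16, length.out = 15),
                                       n_children = 150, seed = 4)
  fit <- fit_gbtm(gen$panel, spec = true$spec, n_starts = 1, seed = 3)
  pred <- predict_trajectory(fit, ages = c(7, 11, 15))
  expect_true(all(pred$mean >= 0 & pred$mean <= 8))
  expect_true(all(pred$lower <= pred$mean & pred$mean <= pred$upper))

  # Monte-Carlo oracle: simulated observations at the fitted parameters
  set.seed(99)
  for (r in sample(nrow(pred), 4)) {
    mu <- sum(sporttraj:::poly_basis(true$spec, pred$age[r]) *
                fit$params$beta[pred$group[r], ])
    sims <- pmin(pmax(rnorm(2e5, mu, fit$params$sigma), 0), 8)
    expect_equal(pred$mean[r], mean(sims), tolerance = 0.02)
  }

  # bands shrink roughly as 1/sqrt(information): scale the data x16
  big <- do.call(rbind, lapply(1:16, function(i) {
    p <- gen$panel
    p$child_id <- paste0(p$child_id, "_", i)
    p
  }))
  fit_big <- fit_gbtm(big, spec = true$spec, n_starts = 1, seed = 3)
  pred_big <- predict_trajectory(fit_big, ages = c(7, 11, 15))
  w_small <- mean(pred$upper - pred$lower)
  w_big <- mean(pred_big$upper - pred_big$lower)
  expect_lt(w_big, w_small / 2)

  expect_warning(predict_trajectory(fit, ages = c(2, 10)), "age range")
})
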