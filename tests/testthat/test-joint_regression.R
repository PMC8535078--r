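test_that("additive data force unit slopes and zero RSS", {
  # rows differ by a constant: no GEI
  y <- rbind(c(1, 3, 5), c(2, 4, 6))
  fit <- fit_joint_regression(y)
  expect_equal(unname(fit$variety_means), c(3, 4))
  expect_equal(unname(fit$sensitivity), c(1, 1))
  expect_equal(unname(fit$env_index), c(-2, 0, 2))
  expect_equal(fit$rss, 0)
  expect_true(fit$exact_fit)
})

test_that("data built exactly from the bilinear model are recovered exactly", {
  V <- c(10, 20)
  b <- c(0.5, 1.5)
  E <- c(-2, 2, 0, 1, -1)
  y <- V + outer(b, E)
  fit <- fit_joint_regression(y)
  expect_equal(unname(fit$variety_means), V, tolerance = 1e-10)
  expect_equal(unname(fit$sensitivity), b, tolerance = 1e-10)
  expect_equal(unname(fit$env_index), E, tolerance = 1e-10)
  expect_true(fit$exact_fit)
})

test_that("complete-data fit matches the rank-1 SVD oracle to 1e-8", {
  for (seed in 1:10) {
    set.seed(seed)
    y <- matrix(rnorm(24, sd = 2), 4, 6)
    fit <- fit_joint_regression(y)
    oracle <- svd_rank1_oracle(y)
    expect_lt(max(abs(outer(fit$sensitivity, fit$env_index) -
                        oracle$bilinear)), 1e-8)
    expect_equal(unname(fit$variety_means), oracle$V, tolerance = 1e-8)
  }
})

test_that("identification constraints hold and the fit is scaling-invariant", {
  set.seed(5)
  y <- matrix(rnorm(40, mean = 8), 4, 10)
  y[2, 3] <- NA # unbalanced too
  fit <- fit_joint_regression(y)
  expect_lt(abs(mean(fit$sensitivity) - 1), 1e-9)
  expect_lt(abs(sum(fit$env_index)), 1e-9)
  # fitted values are invariant under (b/c, cE): refitting scaled starting
  # points must land on the same fitted surface
  expect_equal(fit$fitted,
               fit$variety_means + outer(fit$sensitivity, fit$env_index))
})

test_that("RSS is monotone non-increasing across iterations", {
  for (seed in c(2, 9, 31)) {
    set.seed(seed)
    y <- matrix(rnorm(88, mean = 8, sd = 2), 4, 22)
    fit <- fit_joint_regression(y)
    expect_true(all(diff(fit$rss_trace) <= 1e-8 * (fit$rss_trace[1] + 1)))
    expect_true(fit$converged)
  }
})

test_that("missing cells reduce the error degrees of freedom only", {
  sim <- simulate_met(synthetic_truth(seed = 21, sigma_noise = 0.3))
  y <- cell_means(sim$met, "yield")$values
  full <- fit_joint_regression(y)
  y_miss <- y
  y_miss[1, 1] <- NA
  y_miss[3, 7] <- NA
  part <- fit_joint_regression(y_miss)
  expect_identical(part$n_obs, full$n_obs - 2L)
  expect_identical(part$df_error, full$df_error - 2L)
  expect_true(part$converged)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(fit_joint_regression(matrix(1:6, 1, 6)),
               class = "oatmet_input_error") # g = 1
  expect_error(fit_joint_regression(matrix(1:4, 2, 2)),
               class = "oatmet_input_error") # e = 2
  # no environment spread: all columns identical
  y <- matrix(rep(c(1, 2, 3), times = 4), 3, 4)
  expect_error(fit_joint_regression(y), class = "oatmet_degenerate_error")
  # variety observed in < 3 environments
  y2 <- matrix(rnorm(12), 3, 4)
  y2[1, 1:2] <- NA
  expect_error(fit_joint_regression(y2), class = "oatmet_input_error")
})

test_that("slope heterogeneity test: null at unit slopes, flag at exact fit", {
  # additive data: heterogeneity SS = 0, p = 1
  y <- rbind(c(1, 3, 5), c(2, 4, 6)) + 0
  fit <- fit_joint_regression(y)
  het <- slope_heterogeneity_test(fit)
  expect_equal(het$statistic, 0)
  expect_equal(het$p_value, 1)

  # exact rank-1 data with unequal slopes: exact-fit flag, p = 0
  y2 <- c(10, 20, 15) + outer(c(0.5, 1.6, 0.9), c(-2, 2, 0, 1, -1))
  het2 <- slope_heterogeneity_test(fit_joint_regression(y2))
  expect_true(het2$exact_fit)
  expect_equal(het2$p_value, 0)

  # noisy data with genuinely unequal slopes: strong rejection
  truth <- synthetic_truth(seed = 2, sensitivities = c(0.4, 0.8, 1.2, 1.6),
                           sigma_noise = 0.1)
  sim <- simulate_met(truth)
  het3 <- slope_heterogeneity_test(
    fit_joint_regression(cell_means(sim$met, "yield")))
  expect_lt(het3$p_value, 0.001)
})

test_that("variety effect test separates shifted rows and accepts identical ones", {
  set.seed(4)
  E <- c(-2, -1, 0, 1, 2) * 1.5
  base <- outer(rep(1, 3), E)
  noise <- matrix(rnorm(15, sd = 0.05), 3, 5)

  same <- fit_joint_regression(0 + base + noise)
  expect_gt(variety_effect_test(same)$p_value, 0.05)

  apart <- fit_joint_regression(c(0, 50, 100) + base + noise)
  expect_lt(variety_effect_test(apart)$p_value, 0.001)

  exact <- fit_joint_regression(c(0, 5, 10) + base)
  expect_true(variety_effect_test(exact)$exact_fit)
})

test_that("stability classification uses a t test of b against 1", {
  fake <- structure(list(
    sensitivity = c(B = 1.381, G = 0.988, M = 0.799, T = 0.808),
    se_sensitivity = c(0.05, 0.05, 0.05, 0.05),
    df_error = 60L, exact_fit = FALSE
  ), class = "joint_regression")
  expect_identical(unname(classify_stability(fake)),
                   c("sensitive", "average", "stable", "stable"))

  allone <- structure(list(
    sensitivity = rep(1, 3), se_sensitivity = rep(0.01, 3),
    df_error = 10L, exact_fit = FALSE
  ), class = "joint_regression")
  expect_identical(unname(classify_stability(allone)), rep("average", 3))

  one_sensitive <- structure(list(
    sensitivity = 2, se_sensitivity = 0.01, df_error = 10L,
    exact_fit = FALSE
  ), class = "joint_regression")
  expect_identical(unname(classify_stability(one_sensitive)), "sensitive")
})

test_that("non-convergence is flagged, not thrown", {
  set.seed(8)
  y <- matrix(rnorm(88, mean = 8), 4, 22)
  expect_warning(fit <- fit_joint_regression(y, max_iter = 2L),
                 "did not converge")
  expect_false(fit$converged)
  expect_error(slope_heterogeneity_test(fit), class = "oatmet_input_error")
})

test_that("parameter recovery: exact at zero noise, RMSE small under noise", {
  truth0 <- synthetic_truth(seed = 13, sigma_noise = 0)
  fit0 <- fit_joint_regression(cell_means(simulate_met(truth0)$met, "yield"))
  expect_lt(max(abs(fit0$sensitivity - truth0$sensitivities)), 1e-10)
  expect_lt(max(abs(fit0$env_index - truth0$env_index)), 1e-10)

  sigma_env <- 1.5
  rmse <- vapply(1:25, function(s) {
    truth <- synthetic_truth(seed = s, sigma_env = sigma_env,
                             sigma_noise = 0.3 * sigma_env)
    fit <- fit_joint_regression(cell_means(simulate_met(truth)$met, "yield"))
    sqrt(mean((fit$sensitivity - truth$sensitivities)^2))
  }, numeric(1))
  expect_lt(sqrt(mean(rmse^2)), 0.1)
})
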