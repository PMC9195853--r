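test_that("the mixture model honours its width and asymptote definitions", {
  for (sg in c("cumulative_gaussian", "logistic")) {
    p <- psychometric_params(m = 0, w = 12, sigmoid = sg)
    expect_equal(predict_psychometric(p, 0), 0.5)
    expect_equal(predict_psychometric(p, 6), 0.95)   # S(m + w/2) = 0.95
    expect_equal(predict_psychometric(p, -6), 0.05)  # S(m - w/2) = 0.05
  }
  p <- psychometric_params(0, 10, gamma = 0.1, delta = 0.05)
  expect_equal(predict_psychometric(p, -1e9), 0.1)
  expect_equal(predict_psychometric(p, 1e9), 0.95)

  # non-decreasing and bounded
  x <- seq(-50, 50, length.out = 401)
  pr <- predict_psychometric(p, x)
  expect_true(all(diff(pr) >= 0))
  expect_true(all(pr >= 0.1 & pr <= 0.95))

  expect_error(psychometric_params(0, -1))
  expect_error(psychometric_params(0, 1, gamma = 0.6))
})

test_that("negative log-likelihood matches a per-trial Bernoulli oracle", {
  p <- psychometric_params(205, 40, 0.08, 0.03)
  data <- binomial_data(seq(175, 240, 5), rep(30, 14),
                        c(2, 3, 2, 5, 4, 9, 12, 14, 20, 22, 25, 26, 28, 27))
  probs <- predict_psychometric(p, data$level)
  oracle <- -sum(unlist(purrr::map2(probs, seq_len(nrow(data)), function(pi, i) {
    trials <- c(rep(1, data$k[i]), rep(0, data$n[i] - data$k[i]))
    log(ifelse(trials == 1, pi, 1 - pi))
  })))
  expect_equal(neg_log_likelihood(p, data), oracle, tolerance = 1e-10)

  # closed form: one level at chance
  half <- tibble::tibble(level = 1, n = 30L, k = 15L)
  expect_equal(
    neg_log_likelihood(psychometric_params(1, 5), half), 30 * log(2)
  )

  # clamping keeps saturated predictions finite
  sat <- binomial_data(c(1, 2, 3, 4), rep(10, 4), c(0, 0, 10, 10))
  expect_true(is.finite(
    neg_log_likelihood(psychometric_params(2.5, 1e-6), sat)
  ))
})

test_that("false-alarm correction inverts the guessing mixture", {
  expect_equal(false_alarm_correct(0.2, 0.2), 0)
  expect_equal(false_alarm_correct(c(0.1, 0.7), 0), c(0.1, 0.7))
  expect_error(false_alarm_correct(0.5, 1))
  # corrected 0.5 is attained where raw P = gamma + 0.5 (1 - gamma)
  g <- 0.17
  expect_equal(false_alarm_correct(g + 0.5 * (1 - g), g), 0.5)
})

test_that("corrected thresholds sit at m without lapses and above m with", {
  rng <- c(170, 240)
  expect_equal(
    threshold_from_params(psychometric_params(205, 40), rng), 205,
    tolerance = 1e-6
  )
  # with delta = 0 the correction cancels exactly, for any gamma
  expect_equal(
    threshold_from_params(psychometric_params(205, 40, gamma = 0.2), rng), 205,
    tolerance = 1e-6
  )
  # a positive lapse rate shifts the corrected crossing above m
  thr <- threshold_from_params(psychometric_params(205, 40, 0.2, 0.05), rng)
  expect_gt(thr, 205)
  # numeric root agrees with the closed-form Gaussian inversion
  s <- 40 / (2 * qnorm(0.95))
  thr_closed <- 205 + s * qnorm(0.5 * (1 - 0.2) / (1 - 0.05 - 0.2))
  expect_equal(thr, thr_closed, tolerance = 1e-6)
})

test_that("maximum-likelihood fits recover generating parameters", {
  truth <- psychometric_params(205, 40, 0.1, 0.02)
  lv <- seq(175, 240, 5)
  rec <- recovery_simulation(30, truth, lv, 30, seed = 42, n_starts = 8)
  expect_lt(median(abs(rec$m_hat - 205)), 10) # w / 4
  expect_gt(mean(rec$valid), 0.9)

  # bias and RMSE shrink as trials per level grow
  rec_big <- recovery_simulation(30, truth, lv, 300, seed = 42, n_starts = 8)
  rmse <- function(x) sqrt(mean((x - 205)^2))
  expect_lt(rmse(rec_big$m_hat), rmse(rec$m_hat))
})

test_that("fits classify degenerate data as invalid", {
  lv <- seq(175, 240, 5)
  flat <- binomial_data(lv, rep(30, 14), rep(0, 14))
  f1 <- fit_psychometric(flat, n_starts = 6, seed = 1)
  expect_false(f1$valid)
  expect_identical(f1$invalid_reason, "did_not_reach_half")

  # monotone data reaching 0.5 only at the last level
  k <- c(rep(0, 13), 15)
  f2 <- fit_psychometric(binomial_data(lv, rep(30, 14), k),
                         n_starts = 12, seed = 1)
  expect_false(f2$valid)
  expect_identical(f2$invalid_reason, "threshold_on_limit")

  expect_error(
    fit_psychometric(binomial_data(c(1, 2, 3), rep(10, 3), c(0, 5, 10))),
    "4 stimulus levels"
  )
})

test_that("the ML optimum beats a coarse grid-search oracle", {
  lv <- seq(175, 240, 5)
  truth <- psychometric_params(200, 30, 0.05, 0.02)
  for (s in 1:4) {
    k <- withr::with_seed(s, rbinom(14, 30, predict_psychometric(truth, lv)))
    data <- binomial_data(lv, rep(30, 14), k)
    fit <- fit_psychometric(data, n_starts = 8, seed = s)
    grid <- expand.grid(
      m = seq(175, 240, length.out = 12),
      w = seq(5, 130, length.out = 10),
      gamma = c(0, 0.05, 0.1),
      delta = c(0, 0.05, 0.1)
    )
    grid_best <- min(purrr::pmap_dbl(grid, function(m, w, gamma, delta) {
      neg_log_likelihood(psychometric_params(m, w, gamma, delta), data)
    }))
    expect_lte(fit$neg_log_lik, grid_best + 1e-6)
  }
})

test_that("fits are invariant to affine rescaling of the stimulus axis", {
  lv <- seq(175, 240, 5)
  truth <- psychometric_params(205, 40, 0.08, 0.02)
  k <- withr::with_seed(7, rbinom(14, 30, predict_psychometric(truth, lv)))
  f_native <- fit_psychometric(binomial_data(lv, rep(30, 14), k), seed = 2)
  a <- 0.04
  b <- -3
  f_scaled <- fit_psychometric(binomial_data(a * lv + b, rep(30, 14), k),
                               seed = 2)
  expect_equal(f_scaled$params$m, a * f_native$params$m + b, tolerance = 1e-2)
  expect_equal(f_scaled$params$w, a * f_native$params$w, tolerance = 1e-2)
  expect_equal(f_scaled$neg_log_lik, f_native$neg_log_lik, tolerance = 1e-6)
})

test_that("gamma can be fixed from no-change trials", {
  lv <- seq(175, 240, 5)
  truth <- psychometric_params(205, 40, 0.1, 0.02)
  k <- withr::with_seed(9, rbinom(14, 30, predict_psychometric(truth, lv)))
  fit <- fit_psychometric(binomial_data(lv, rep(30, 14), k), fix_gamma = 0.1,
                          n_starts = 8, seed = 3)
  expect_equal(fit$params$gamma, 0.1)
  expect_true(fit$valid)
})

test_that("fit accessors expose tidy and glance summaries", {
  lv <- seq(175, 240, 5)
  truth <- psychometric_params(205, 40, 0.05, 0.02)
  k <- withr::with_seed(3, rbinom(14, 30, predict_psychometric(truth, lv)))
  fit <- fit_psychometric(binomial_data(lv, rep(30, 14), k), n_starts = 8)
  td <- tidy(fit)
  expect_identical(td$term, c("m", "w", "gamma", "delta"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$n_trials == 420)
  expect_s3_class(autoplot(fit), "ggplot")
})
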