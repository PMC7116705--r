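test_that("autocovariance uses divisor T and optional mean correction", {
  x <- c(1, -1, 1, -1)
  g <- autocovariance(x, 1)
  expect_equal(g, c(1, -0.75))

  expect_equal(autocovariance(rep(3, 10), 2, demean = TRUE), c(0, 0, 0))

  y <- rnorm(20)
  expect_equal(autocovariance(y, 0), mean(y^2))
  expect_equal(autocovariance(y, 3, demean = TRUE, center = 0),
               autocovariance(y, 3))
  expect_error(autocovariance(y, 20), "smaller than the series length")
})

test_that("pooled autocovariance combines moment sums over T1 + T2", {
  x <- c(1, -1, 1, -1)
  y <- c(2, -2, 2, -2)
  pc <- pooled_autocovariance(x, y, 1)
  expect_equal(pc$values[1], 2.5)             # (4 + 16) / 8
  expect_equal(pc$values[2], (-3 + -12) / 8)

  z <- rnorm(30)
  expect_equal(pooled_autocovariance(z, z, 4)$values, autocovariance(z, 4))

  const <- pooled_autocovariance(rep(5, 8), rep(5, 12), 2, demean = TRUE)
  expect_equal(const$values, c(0, 0, 0))
  expect_equal(const$pooled_mean, 5)

  # pooled mean weights the two segments by length
  a <- rep(0, 10); b <- rep(4, 30)
  expect_equal(pooled_autocovariance(a, b, 1, demean = TRUE)$pooled_mean, 3)
  expect_error(pooled_autocovariance(a, b, 15), "shorter segment")
})

test_that("Levinson-Durbin solves the Yule-Walker equations", {
  f <- levinson_durbin(c(1, 0), 1)
  expect_equal(f$coeffs, 0)
  expect_equal(f$innovation_var, 1)

  f <- levinson_durbin(c(1, -0.75), 1)
  expect_equal(f$coeffs, 0.75)
  expect_equal(f$innovation_var, 0.4375)

  expect_error(levinson_durbin(c(0, 0), 1), "not positive")
  expect_error(levinson_durbin(c(1, 1.2), 1), "positive definite")
})

test_that("Levinson-Durbin matches the direct Toeplitz solve", {
  set.seed(401)
  for (rep in 1:200) {
    p <- sample(1:10, 1)
    g <- random_acv(p, n = sample(40:120, 1))
    ld <- levinson_durbin(g, p)
    direct <- toeplitz_ar_fit(g, p)
    expect_equal(ld$coeffs, direct$coeffs, tolerance = 1e-10)
    expect_equal(ld$innovation_var, direct$innovation_var, tolerance = 1e-10)
  }
})

test_that("innovation variance is non-increasing in the order", {
  set.seed(402)
  for (rep in 1:20) {
    g <- random_acv(8)
    path <- levinson_durbin(g, 8)$sigma2_by_order
    expect_true(all(diff(path) <= 1e-12))
  }
})

test_that("conditional log-likelihood has the Gaussian closed forms", {
  wn <- structure(list(order = 0L, coeffs = numeric(0), innovation_var = 1),
                  class = "ar_fit")
  expect_equal(ar_conditional_loglik(c(0, 0, 0), wn), -1.5 * log(2 * pi))

  # doubling the innovation variance at fixed residuals: closed-form change
  set.seed(403)
  x <- rnorm(50)
  f1 <- structure(list(order = 1L, coeffs = -0.3, innovation_var = 2),
                  class = "ar_fit")
  f2 <- f1; f2$innovation_var <- 4
  rss <- sum((x[2:50] - 0.3 * x[1:49])^2)
  expect_equal(ar_conditional_loglik(x, f2) - ar_conditional_loglik(x, f1),
               -0.5 * 49 * log(2) + rss / 4 - rss / 8)
})

test_that("conditional log-likelihood is additive over a window partition", {
  set.seed(404)
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.2)), 300))
  fit <- levinson_durbin(autocovariance(x, 2), 2)
  # right part conditions on lags before its start, so the sum telescopes
  whole <- ar_conditional_loglik(x, fit, 1, 300)
  left <- ar_conditional_loglik(x, fit, 1, 120)
  right <- ar_conditional_loglik(x, fit, 121, 300)
  expect_equal(whole, left + right)
})

test_that("the fitted parameters approximately maximize the likelihood", {
  x <- simulate_segment(segment_spec(ar = 0.6, length = 5000), seed = 11)
  fit <- levinson_durbin(autocovariance(x, 1), 1)
  base <- ar_conditional_loglik(x, fit)
  for (delta in c(-0.05, 0.05)) {
    pert <- fit
    pert$coeffs <- fit$coeffs + delta
    expect_lt(ar_conditional_loglik(x, pert), base)
  }
})

test_that("fixed-order rule floors the squared base-10 log", {
  expect_identical(fixed_order(128), 4L)
  expect_identical(fixed_order(100), 4L)   # log10 = 2 exactly
  expect_identical(fixed_order(53), 2L)    # just below 10^sqrt(3)
  expect_identical(fixed_order(54), 3L)    # just above 10^sqrt(3)
  expect_identical(fixed_order(200), 5L)
  # configurable base and exponent
  expect_identical(fixed_order(128, upsilon = 2, log_base = exp(1)), 23L)
  expect_identical(fixed_order(128, upsilon = 1.5), 3L)
  expect_error(fixed_order(1), "at least 2")
})
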