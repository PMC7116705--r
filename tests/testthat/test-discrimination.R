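test_that("identical segments give Lambda = 0 and p = 1", {
  x <- simulate_segment(segment_spec(ar = 0.5, length = 300), seed = 1)
  for (variant in c("zero_mean", "mean_corrected", "known_order")) {
    res <- discrimination_test(x, x, variant = variant)
    expect_equal(res$lambda, 0)
    expect_equal(res$p_value, 1)
  }
})

test_that("the statistic is symmetric and scale-invariant", {
  x <- simulate_segment(segment_spec(ar = 0.4, length = 250), seed = 2)
  y <- simulate_segment(segment_spec(ar = -0.3, length = 180), seed = 3)
  a <- discrimination_test(x, y)
  b <- discrimination_test(y, x)
  expect_equal(a$lambda, b$lambda)
  expect_identical(a$df, b$df)
  scaled <- discrimination_test(3.7 * x, 3.7 * y)
  expect_equal(scaled$lambda, a$lambda)
})

test_that("degrees of freedom follow the variant's rule", {
  x <- rnorm(128); y <- rnorm(128)   # T_min = 128 -> fixed order 4
  expect_identical(discrimination_test(x, y)$df, 5L)
  expect_identical(discrimination_test(x, y, variant = "mean_corrected")$df, 6L)
  ko <- discrimination_test(x, y, variant = "known_order")
  expect_identical(ko$df, ko$order_x + ko$order_y - ko$order_common + 1L)
})

test_that("the mean-corrected variant flags level shifts; the default does not", {
  x <- simulate_segment(segment_spec(ar = 0.5, length = 300), seed = 4)
  y <- simulate_segment(segment_spec(ar = 0.5, length = 300), seed = 5) + 10
  default <- discrimination_test(x - mean(x), y - mean(y))
  shifted <- discrimination_test(x, y, variant = "mean_corrected")
  expect_gt(default$p_value, 0.01)
  expect_lt(shifted$p_value, 1e-10)
})

test_that("the test has power against a genuine AR change", {
  rej <- 0
  for (i in 1:100) {
    x <- simulate_segment(segment_spec(ar = 0.4, length = 200),
                          seed = sub_seed_pair(21, i, 1))
    y <- simulate_segment(segment_spec(ar = -0.6, length = 200),
                          seed = sub_seed_pair(21, i, 2))
    rej <- rej + (discrimination_test(x, y)$p_value < 0.05)
  }
  expect_gt(rej / 100, 0.9)
})

test_that("the null rejection rate is not grossly miscalibrated", {
  rej <- 0
  for (i in 1:200) {
    x <- simulate_segment(segment_spec(ar = 0.5, length = 200),
                          seed = sub_seed_pair(22, i, 1))
    y <- simulate_segment(segment_spec(ar = 0.5, length = 200),
                          seed = sub_seed_pair(22, i, 2))
    x <- x - mean(x); y <- y - mean(y)
    rej <- rej + (discrimination_test(x, y)$p_value < 0.05)
  }
  expect_lt(rej / 200, 0.12)
  expect_gt(rej / 200, 0.005)
})

test_that("segment too short for the fixed order raises an actionable error", {
  expect_error(discrimination_test(rnorm(300), rnorm(3)), "reject this candidate")
})

test_that("candidates are tested against neighbour-delimited segments", {
  sim <- simulate_piecewise(model_library("C"), seed = 42)
  res <- validate_candidates(sim$values, c(400, 612))
  expect_length(res, 2)
  expect_true(all(vapply(res, `[[`, numeric(1), "p_value") < 0.05))
  # first test: segments (1..400) vs (401..612); second: (401..612) vs (613..1024)
  expect_identical(res[[1]]$n_x, 400L)
  expect_identical(res[[1]]$n_y, 212L)
  expect_identical(res[[2]]$n_y, 412L)

  expect_identical(validate_candidates(sim$values, integer(0)), list())

  # a candidate with an unusably short flank gets p = 1 with a warning
  expect_warning(short <- validate_candidates(rnorm(1000), c(3, 500)),
                 "p-value 1")
  expect_equal(short[[1]]$p_value, 1)
  expect_lt(short[[2]]$p_value, 1)
})
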