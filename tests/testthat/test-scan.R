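test_that("window radius rules match the tabulated values", {
  expect_identical(window_radius(1024, 2), 96L)
  expect_identical(window_radius(1024, 1), 48L)
  expect_identical(window_radius(1024, 1.5), 72L)
  expect_identical(window_radius(1024, 2.5), 120L)
  expect_identical(window_radius(256, 1), 30L)
  expect_identical(window_radius(256, 2), 60L)
  expect_error(window_radius(100, 5), "no scanning positions")
  expect_identical(default_window(2048), 116L)
  expect_identical(default_window(300), 64L)   # 2 * floor(ln(300)^2)
  expect_identical(default_window(148), 50L)   # floor of 50 kicks in
  expect_error(default_window(90), "no scanning positions")
})

test_that("compiled and reference scan engines agree", {
  for (seed in 1:3) {
    sim <- simulate_piecewise(model_library("C"), seed = seed)
    x <- sim$values[1:400]
    a <- scan_profile(x, 50)
    b <- scan_profile(x, 50, engine = "r")
    expect_equal(a$values, b$values, tolerance = 1e-10)
    expect_identical(a$order_used, b$order_used)
  }
  w <- simulate_segment(segment_spec(length = 300), seed = 4)
  expect_equal(scan_profile(w, 40)$values,
               scan_profile(w, 40, engine = "r")$values, tolerance = 1e-10)
})

test_that("the scan statistic is a non-negative likelihood ratio", {
  cases <- list(
    simulate_segment(segment_spec(length = 400), seed = 1),
    simulate_segment(segment_spec(ar = 0.9, length = 400), seed = 2),
    simulate_piecewise(model_library("I"), seed = 3)$values,
    sin(seq(0, 20, length.out = 400)) + rnorm(400, sd = 0.1),
    cumsum(rnorm(400))
  )
  for (x in cases) {
    prof <- scan_profile(x, 40)
    expect_true(all(prof$values >= 0))
    expect_length(prof$values, length(x) - 2 * 40 + 1)
  }
})

test_that("scanning is invariant to a level shift", {
  x <- simulate_piecewise(model_library("D"), seed = 5)$values
  expect_equal(scan_profile(x, 48)$values, scan_profile(x + 100, 48)$values)
})

test_that("the scan localizes an abrupt AR change", {
  hits <- 0
  for (seed in 1:10) {
    sim <- simulate_piecewise(model_library("D"), seed = seed)
    prof <- scan_profile(sim$values, 48)
    argmax <- prof$positions[which.max(prof$values)]
    hits <- hits + (abs(argmax - 50) <= 10)
  }
  expect_gte(hits, 8)
})

test_that("candidates are local maximizers with ties to the smallest index", {
  # single interior peak
  v <- c(1, 2, 5, 2, 1, 0.5, 0.2, 0.1, 0.3, 0.2)
  cand <- select_candidates(make_profile(v, h = 4))
  expect_identical(cand$change_points, 6L)   # position of the peak (h + 2)

  # monotone increasing profile: single candidate at the right edge
  cand <- select_candidates(make_profile(seq(0.1, 1, length.out = 12), h = 5))
  expect_identical(cand$change_points, 16L)

  # two equal peaks closer than h: the earlier one wins
  v <- c(0, 3, 0, 3, 0, 0)
  cand <- select_candidates(make_profile(v, h = 4))
  expect_identical(cand$change_points, 5L)

  # empty profile
  empty <- make_profile(numeric(0), h = 4)
  expect_identical(select_candidates(empty)$change_points, integer(0))
})

test_that("candidate separation and count obey the window radius", {
  for (seed in 1:5) {
    x <- simulate_piecewise(model_library("G"), seed = seed)$values
    prof <- scan_profile(x, 60)
    k <- select_candidates(prof)$change_points
    if (length(k) > 1) expect_true(all(diff(k) >= 60))
    expect_true(all(k >= 60 & k <= length(x) - 60))
    expect_lte(length(k), ceiling((length(x) - 2 * 60 + 1) / 60))
  }
})

test_that("degenerate windows yield LS = 0 with a warning", {
  x <- c(rep(0, 120), rnorm(120))
  expect_warning(prof <- scan_profile(x, 40, center = FALSE), "degenerate")
  expect_true(all(prof$values >= 0))
})
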