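# The independent loop oracles (oracle_scalars, oracle_deriv,
# oracle_integral) live in helper-oracles.R and are shared with the
# acceptance suite.

test_that("worked scalar-feature examples evaluate as computed by hand", {
  f <- time_domain_features(c(-1, 0, 1, 0, 0))
  expect_equal(f[["maximum"]], 1)
  expect_equal(f[["minimum"]], -1)
  expect_equal(f[["mean"]], 0)
  expect_equal(f[["variance"]], 0.4)
  expect_equal(f[["rms"]], sqrt(0.4))
  expect_equal(f[["amplitude"]], 2)
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["kurtosis"]], 2.5)
  expect_equal(f[["area"]], 1.5)

  g <- time_domain_features(c(1, 0, -1, 0, 1))
  expect_equal(g[["decline_slope"]], -1)   # max at t=0, min at t=2
  expect_equal(g[["rising_slope"]], 1)     # next max at t=4

  expect_error(time_domain_features(rep(2, 5)), class = "swp_moment_error")

  # minimum at the final sample: fallback warning, rising slope undefined
  expect_warning(h <- time_domain_features(c(1, 0, -1)),
                 class = "swp_warning")
  expect_true(is.na(h[["rising_slope"]]))
})

test_that("derivative and integral match their worked examples", {
  expect_equal(first_derivative(2 * (0:10)), rep(2, 11))
  expect_equal(first_derivative(rep(4, 6)), rep(0, 6))
  expect_equal(first_derivative(c(0, 1, 4)), c(1, 2, 3))
  expect_equal(cumulative_integral(rep(1, 5)), c(0, 1, 2, 3, 4))
  expect_equal(cumulative_integral(rep(0, 5)), rep(0, 5))
  expect_equal(cumulative_integral(as.numeric(0:4)), c(0, 0.5, 2, 4.5, 8))
})

test_that("all features match independent loop oracles on random vectors", {
  set.seed(101)
  for (k in 1:1000) {
    n <- sample(10:80, 1)
    x <- rnorm(n)
    if (which.min(x) < n)   # the post-minimum-maximum fallback is tested separately
      expect_equal(time_domain_features(x), oracle_scalars(x),
                   tolerance = 1e-12)
    expect_equal(first_derivative(x), oracle_deriv(x), tolerance = 1e-12)
    expect_equal(cumulative_integral(x), oracle_integral(x),
                 tolerance = 1e-12)
  }
})

test_that("derivative of the cumulative integral recovers locally linear traces", {
  # the two discrete operators compose to y_i + (y_{i+1} - 2 y_i + y_{i-1})/4
  # at interior points, i.e. the identity wherever the trace is locally
  # linear; assert away from the kinks of a piecewise-linear trace.
  y <- c(seq(0, 10, length.out = 21), seq(10, -5, length.out = 31)[-1],
         seq(-5, -5, length.out = 10))
  rec <- first_derivative(cumulative_integral(y))
  interior <- setdiff(2:(length(y) - 1), c(20, 21, 22, 50, 51, 52))
  expect_equal(rec[interior], y[interior], tolerance = 1e-9)
})

test_that("scalar features respond to zero-padding only where expected", {
  set.seed(5)
  x <- runif(40, -1, 1)           # 0 interior to the range
  xp <- c(x, rep(0, 20))
  f <- time_domain_features(x)
  fp <- time_domain_features(xp)
  # extremes and amplitude are padding-invariant when 0 is interior
  expect_equal(fp[["maximum"]], f[["maximum"]])
  expect_equal(fp[["minimum"]], f[["minimum"]])
  expect_equal(fp[["amplitude"]], f[["amplitude"]])
  # moments are not: the mean moves toward zero
  expect_false(isTRUE(all.equal(fp[["mean"]], f[["mean"]])))
})

test_that("feature matrices have the documented shapes and order", {
  traces <- tiny_traces(8)
  fd <- build_feature_matrix(traces, "deriv_1st")
  expect_equal(dim(fd$matrix), c(length(traces), 411))
  ft <- build_feature_matrix(traces, "time_domain")
  expect_equal(dim(ft$matrix), c(length(traces), 12))
  expect_equal(colnames(ft$matrix), time_domain_feature_names())
  fi <- build_feature_matrix(traces, "integral")
  expect_equal(dim(fi$matrix), c(length(traces), 411))
  expect_equal(fd$labels,
               vapply(traces, function(t) t$condition, character(1)))

  expect_equal(dim(build_feature_matrix(list(), "deriv_1st")$matrix),
               c(0, 0))
  mixed <- list(make_trace(rnorm(10)), make_trace(rnorm(11)))
  expect_error(build_feature_matrix(mixed, "deriv_1st"),
               class = "swp_shape_error")
})
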