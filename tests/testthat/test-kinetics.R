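# Slopes, T50 and their invariances.

line_trace <- function(t, v) tibble::tibble(time_h = t, value = v)

test_that("a noiseless linear decline returns its exact slope with r^2 = 1", {
  t <- seq(0, 5, 0.1)
  tr <- line_trace(t, 3.2 - 0.5 * t)
  res <- capacitance_slope(tr, upper = 3, lower = 1.5)
  expect_equal(res$slope, 0.5, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  # crossing times by interpolation: value = 3 at t = 0.4, = 1.5 at t = 3.4
  expect_equal(res$t_upper_h, 0.4, tolerance = 1e-12)
  expect_equal(res$t_lower_h, 3.4, tolerance = 1e-12)
})

test_that("noisy-slope estimate equals the closed-form OLS oracle", {
  set.seed(7)
  t <- seq(0, 6, 0.05)
  v <- (3.2 - 0.4 * t) * (1 + 0.01 * rnorm(length(t)))
  tr <- line_trace(t, v)
  res <- capacitance_slope(tr, upper = 3, lower = 1.5)
  keep <- v >= 1.5 & v <= 3
  expect_equal(res$slope, abs(oracle_ols(t[keep], v[keep])$slope),
               tolerance = 1e-10)
})

test_that("missing threshold crossings raise errors naming the threshold", {
  t <- seq(0, 5, 0.1)
  expect_error(capacitance_slope(line_trace(t, 2.8 - 0.3 * t), 3, 1.5),
               "upper threshold 3")
  expect_error(capacitance_slope(line_trace(t, 3.2 - 0.1 * t), 3, 1.5),
               "lower threshold 1.5")
  expect_error(capacitance_slope(line_trace(t, 3.2 - 0.1 * t), 1.5, 3),
               "exceed")
})

test_that("an exact baseline-ramp-plateau trace returns the ramp slope", {
  t <- seq(0, 8, 0.05)
  v <- 2000 + 2000 * pmin(pmax(t - 1, 0), 4)   # 2000 -> 10000 over 4 h
  res <- resistance_slope(line_trace(t, v))
  expect_equal(res$slope, 2000, tolerance = 1e-9)
  expect_equal(res$baseline, 2000)
  expect_equal(res$plateau, 10000)
  expect_true(res$saturated)
})

test_that("the central regression slope of a logistic rise approximates its analytic maximum", {
  # R(t) = base + A plogis((t - t0)/s): max derivative A/(4 s) at t0
  t <- seq(0, 10, 0.02)
  base <- 2000; A <- 8000; s <- 0.8; t0 <- 5
  tr <- line_trace(t, base + A * plogis((t - t0) / s))
  # a central (0.3, 0.7) window, where the logistic is nearly linear,
  # approximates the peak slope; the default wide window averages lower
  res <- resistance_slope(tr, baseline_frac = 0.3, plateau_frac = 0.7)
  analytic <- A / (4 * s)
  expect_lt(abs(res$slope - analytic) / analytic, 0.05)
  wide <- resistance_slope(tr)
  expect_lt(wide$slope, res$slope)
})

test_that("an unsaturated trace warns and still reports a slope", {
  t <- seq(0, 3, 0.05)
  v <- 2000 + 2000 * t   # still rising at the end
  expect_warning(res <- resistance_slope(line_trace(t, v)), "unsaturated")
  expect_false(res$saturated)
  expect_gt(res$slope, 0)
})

test_that("T50 of a symmetric logistic is its centre", {
  t <- seq(0, 3, 0.05)
  tr <- line_trace(t, 2000 + 8000 * plogis((t - 1.5) / 0.15))
  expect_equal(trace_t50(tr)$t50_h, 1.5, tolerance = 0.05)
})

test_that("T50 interpolates linearly between bracketing samples", {
  # midpoint (150) crossed between the samples at t = 2.0 and t = 2.2
  t <- c(0, 1, 2, 2.2, 3, 4, 5, 6, 7, 8, 9, 10)
  v <- c(100, 100, 140, 180, 200, 200, 200, 200, 200, 200, 200, 200)
  got <- trace_t50(line_trace(t, v), k = 2)$t50_h
  # hand interpolation: 140 + (150-140)/(180-140) * (2.2-2.0) on the t axis
  expect_equal(got, 2 + (150 - 140) / (180 - 140) * 0.2, tolerance = 1e-12)
})

test_that("T50 honours the fence-off time origin", {
  tr <- simulate_migration("control", noise_sd = 0, fence_off_h = 10)
  t50_attr <- trace_t50(tr)$t50_h           # origin from the attribute
  t50_abs <- trace_t50(tr, t0 = 0)$t50_h    # absolute time
  expect_equal(t50_abs - t50_attr, 10, tolerance = 1e-9)
})

test_that("a flat trace has undefined T50 and a non-crossing trace errors", {
  t <- seq(0, 2, 0.1)
  expect_error(trace_t50(line_trace(t, rep(5, length(t)))), "undefined")
})

test_that("slope and T50 transform correctly under time shifts and value scaling", {
  set.seed(11)
  t <- seq(0, 8, 0.05)
  v <- (2000 + 2000 * pmin(pmax(t - 1, 0), 4)) * (1 + 0.005 * rnorm(length(t)))
  base <- line_trace(t, v)
  shift <- line_trace(t + 2.5, v)
  scaled <- line_trace(t, 3 * v)
  expect_equal(resistance_slope(shift)$slope, resistance_slope(base)$slope,
               tolerance = 1e-12)
  # absolute crossing time shifts with the clock; the default origin (trace
  # start) makes the relative T50 shift-invariant
  expect_equal(trace_t50(shift, t0 = 0)$t50_h - trace_t50(base, t0 = 0)$t50_h,
               2.5, tolerance = 1e-9)
  expect_equal(trace_t50(shift)$t50_h, trace_t50(base)$t50_h,
               tolerance = 1e-9)
  expect_equal(resistance_slope(scaled)$slope, 3 * resistance_slope(base)$slope,
               tolerance = 1e-12)
  expect_equal(trace_t50(scaled)$t50_h, trace_t50(base)$t50_h,
               tolerance = 1e-12)
})
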