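# Inverse fit: interface calibration and (Rb, alpha, Cm) recovery.

test_that("noiseless synthetic scans round-trip the generating parameters", {
  el <- ref_electrode()
  truth <- ref_cells()
  covered <- simulate_scan(el, truth, noise_sd = 0, seed = 1)
  free <- simulate_scan(el, NULL, noise_sd = 0, seed = 2)
  fit <- fit_cell_params(covered, free, el, rc_um = 11.72, n_starts = 6,
                         seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$rb_ohm_cm2 - truth$rb_ohm_cm2) / truth$rb_ohm_cm2, 0.01)
  expect_lt(abs(fit$params$h_nm - truth$h_nm) / truth$h_nm, 0.01)
  expect_lt(abs(fit$params$cm_uf_cm2 - truth$cm_uf_cm2) / truth$cm_uf_cm2, 0.01)
  td <- tidy(fit)
  expect_equal(td$term, c("rb", "alpha", "h", "cm"))
  expect_equal(td$estimate[3], fit$params$h_nm)
  expect_equal(glance(fit)$n_freq, 25L)
})

test_that("a covered scan identical to the free scan drives Rb and alpha to the lower bound", {
  el <- ref_electrode()
  free <- simulate_scan(el, NULL, noise_sd = 0, seed = 3)
  bounds <- list(rb = c(1e-3, 100), h = c(1, 2000), cm = c(0.1, 20))
  fit <- fit_cell_params(free, free, el, rc_um = 11.72, bounds = bounds,
                         n_starts = 6, seed = 1)
  expect_equal(fit$params$rb_ohm_cm2, bounds$rb[1], tolerance = 1e-6)
  # alpha lower bound corresponds to the h upper bound
  expect_equal(fit$params$alpha, h_to_alpha(bounds$h[2], 54, 11.72),
               tolerance = 1e-6)
  # the optimum beats every multi-start interior point
  expect_true(all(fit$residual <= fit$starts$residual + 1e-12))
})

test_that("parameter recovery holds across the physiological box at zero noise", {
  el <- ref_electrode()
  set.seed(42)
  n_draw <- 12
  rb <- exp(stats::runif(n_draw, log(0.5), log(10)))
  h <- exp(stats::runif(n_draw, log(20), log(100)))
  cm <- exp(stats::runif(n_draw, log(0.5), log(4)))
  free <- simulate_scan(el, NULL, noise_sd = 0, seed = 99)
  for (i in seq_len(n_draw)) {
    truth <- cell_params(rb[i], h_nm = h[i], cm_uf_cm2 = cm[i], rc_um = 11.72)
    covered <- simulate_scan(el, truth, noise_sd = 0, seed = 1000 + i)
    fit <- fit_cell_params(covered, free, el, rc_um = 11.72, n_starts = 4,
                           seed = i)
    expect_lt(abs(fit$params$rb_ohm_cm2 - rb[i]) / rb[i], 0.01)
    expect_lt(abs(fit$params$h_nm - h[i]) / h[i], 0.01)
    expect_lt(abs(fit$params$cm_uf_cm2 - cm[i]) / cm[i], 0.01)
  }
})

test_that("fit is deterministic given the seed and equivariant under impedance scaling", {
  el <- ref_electrode()
  truth <- ref_cells()
  covered <- simulate_scan(el, truth, noise_sd = 0.01, seed = 11)
  free <- simulate_scan(el, NULL, noise_sd = 0.01, seed = 12)
  f1 <- fit_cell_params(covered, free, el, rc_um = 11.72, n_starts = 4, seed = 5)
  f2 <- fit_cell_params(covered, free, el, rc_um = 11.72, n_starts = 4, seed = 5)
  expect_identical(tidy(f1)$estimate, tidy(f2)$estimate)

  # the model family is closed under a global gain c with
  # (Rb, alpha, Cm) -> (c Rb, sqrt(c) alpha, Cm / c); a gain error therefore
  # moves the estimates by exactly this law (absolute calibration matters)
  cgain <- 3
  scale_scan <- function(s) {
    s$z_real_ohm <- s$z_real_ohm * cgain
    s$z_imag_ohm <- s$z_imag_ohm * cgain
    s
  }
  f3 <- fit_cell_params(scale_scan(covered), scale_scan(free), el,
                        rc_um = 11.72, n_starts = 4, seed = 5)
  expect_equal(f3$params$rb_ohm_cm2, cgain * f1$params$rb_ohm_cm2,
               tolerance = 1e-3)
  expect_equal(f3$params$alpha, sqrt(cgain) * f1$params$alpha,
               tolerance = 1e-3)
  expect_equal(f3$params$cm_uf_cm2, f1$params$cm_uf_cm2 / cgain,
               tolerance = 1e-3)
})

test_that("mismatched frequency grids and bad bounds are rejected", {
  el <- ref_electrode()
  covered <- simulate_scan(el, ref_cells(), seed = 1)
  free <- simulate_scan(el, NULL, seed = 2,
                        frequencies = scan_frequencies(20))
  expect_error(fit_cell_params(covered, free, el), "identical frequency grid")
  free25 <- simulate_scan(el, NULL, seed = 2)
  expect_error(fit_cell_params(covered, free25, el,
                               bounds = list(rb = c(2, 1), h = c(1, 2000),
                                             cm = c(0.1, 20))),
               "bounds")
})
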